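#' Numerically stable binary cross-entropy on logits
#'
#' Computes \eqn{-[y \log s(x) + (1-y) \log(1 - s(x))]} with \eqn{s} the
#' logistic sigmoid, in the overflow-free form
#' \eqn{\max(x,0) - xy + \log(1 + e^{-|x|})}.  Stable for logits far
#' outside the range where `exp` overflows.
#'
#' @param logits raw scores (any numeric shape).
#' @param targets targets in `[0, 1]`, same shape as `logits`.
#' @return elementwise losses, same shape as the inputs.
#' @export
bce_with_logits <- function(logits, targets) {
  if (length(logits) != length(targets))
    stop("logits and targets must have the same length")
  pmax(logits, 0) - logits * targets + log1p(exp(-abs(logits)))
}

#' Classification loss over positive matches
#'
#' Per-class binary cross-entropy of the logistic sigmoid of the class
#' logits against 0/1 class indicators, summed over predictions and
#' classes and normalized by the positive-sample count \eqn{N_{pos}}:
#' \eqn{L_{CLS} = -\frac{1}{N_{pos}} \sum_{ij} [y_{ij}\log s(x_{ij}) +
#' (1-y_{ij}) \log(1-s(x_{ij}))]}.
#'
#' @param logits numeric matrix of raw class scores, one row per positive
#'   prediction, one column per class (a vector is treated as one class).
#' @param labels 0/1 indicator matrix of the same shape.
#' @param n_pos positive-sample count; defaults to the number of
#'   predictions (rows).  `n_pos = 0` with empty inputs yields 0 with a
#'   warning.
#' @return the scalar classification loss.
#' @export
classification_loss <- function(logits, labels, n_pos = NULL) {
  logits <- as.matrix(logits); labels <- as.matrix(labels)
  if (!all(dim(logits) == dim(labels)))
    stop("logits and labels must have identical dimensions")
  if (length(labels) && !all(labels %in% c(0, 1)))
    stop("labels must be binary (0/1)")
  if (is.null(n_pos)) n_pos <- nrow(logits)
  if (n_pos == 0) {
    if (length(logits))
      stop("n_pos = 0 with non-empty logits is inconsistent")
    warning("no positive samples in batch; classification loss is 0")
    return(0)
  }
  sum(bce_with_logits(logits, labels)) / n_pos
}

#' Objectness (target-confidence) loss
#'
#' Binary cross-entropy of the sigmoid of each prediction's objectness
#' logit against a soft target: the IoU between the prediction box and its
#' matched ground-truth box (0 for negatives).  Averaged over \eqn{N}, the
#' total number of positive plus negative samples.
#'
#' @param logits numeric vector of objectness logits, one per prediction.
#' @param iou_targets targets in `[0, 1]`, one per prediction.
#' @param n normalizer \eqn{N}; defaults to `length(logits)`.
#' @return the scalar objectness loss.
#' @export
objectness_loss <- function(logits, iou_targets, n = NULL) {
  logits <- as.numeric(logits); iou_targets <- as.numeric(iou_targets)
  if (length(logits) != length(iou_targets))
    stop("logits and iou_targets must have the same length")
  if (length(logits) == 0L) stop("objectness loss needs at least one sample")
  if (any(iou_targets < 0 | iou_targets > 1))
    stop("iou_targets must lie in [0, 1]")
  if (is.null(n)) n <- length(logits)
  if (n < 1) stop("n must be >= 1")
  sum(bce_with_logits(logits, iou_targets)) / n
}

#' Loss weights for the composite detection loss
#'
#' @param a classification weight.
#' @param b objectness weight.
#' @param c box-regression weight.
#' @return a list with elements `a`, `b`, `c`.
#' @export
loss_weights <- function(a = 0.5, b = 1.0, c = 0.05) {
  w <- c(a = a, b = b, c = c)
  if (anyNA(w) || any(!is.finite(w)) || any(w < 0))
    stop("loss weights must be finite and non-negative")
  as.list(w)
}

#' Composite detection loss
#'
#' \eqn{L = a L_{CLS} + b L_{OBJ} + c L_{BOX}}.  The returned breakdown
#' retains the unweighted components alongside the weighted total.
#'
#' @param l_cls,l_obj,l_box the three component losses (finite,
#'   non-negative scalars).
#' @param weights see [loss_weights()].
#' @return a list of class `loss_breakdown` with elements `l_cls`,
#'   `l_obj`, `l_box`, `total`.
#' @export
total_loss <- function(l_cls, l_obj, l_box, weights = loss_weights()) {
  comp <- c(l_cls = l_cls, l_obj = l_obj, l_box = l_box)
  if (anyNA(comp) || any(!is.finite(comp)) || any(comp < 0))
    stop("loss components must be finite and non-negative")
  structure(
    list(l_cls = l_cls, l_obj = l_obj, l_box = l_box,
         total = weights$a * l_cls + weights$b * l_obj + weights$c * l_box),
    class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("detection loss: total %.6g (cls %.6g | obj %.6g | box %.6g)\n",
              x$total, x$l_cls, x$l_obj, x$l_box))
  invisible(x)
}
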