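#' SIoU loss parameters
#'
#' The SIoU box-regression loss augments plain IoU with an angle cost, a
#' distance cost modulated by the angle cost, and a shape cost.  The shape
#' cost carries an attention exponent `theta` controlling how strongly
#' width/height mismatch is penalized relative to center placement; the
#' admissible range is `[2, 6]` and the default is 4.
#'
#' @param theta shape-cost attention exponent; values outside `[2, 6]` are
#'   clamped with a warning.
#' @return a list with element `theta`.
#' @export
siou_params <- function(theta = 4) {
  theta <- as.numeric(theta)
  if (length(theta) != 1L || !is.finite(theta))
    stop("theta must be a single finite number")
  if (theta < 2 || theta > 6) {
    warning("theta clamped to [2, 6]")
    theta <- min(max(theta, 2), 6)
  }
  list(theta = theta)
}

# Division guard for coincident centers (sigma ~ 0).
.siou_eps <- 1e-9

#' Angle cost of the SIoU loss
#'
#' \eqn{\Lambda = 1 - 2 \sin^2(\arcsin(c_h/\sigma) - \pi/4)} where
#' \eqn{c_h} is the absolute vertical gap between the two box centers and
#' \eqn{\sigma} their Euclidean distance.  Equivalently
#' \eqn{\Lambda = \sin(2\alpha)} with \eqn{\sin\alpha = c_h/\sigma}: the
#' cost is 0 when the centers are axis-aligned (\eqn{\alpha = 0} or
#' \eqn{\pi/2}) and 1 when they sit at 45 degrees.  The implementation
#' evaluates the closed form
#' \eqn{\sin(2\alpha) = 2 c_h c_w / \sigma^2} (with \eqn{c_w} the
#' horizontal center gap), which is algebraically identical and exact in
#' the axis-aligned and 45-degree cases.  Coincident centers
#' (\eqn{\sigma \le \epsilon}) return 0 by convention.
#'
#' @param pred,gt predicted and ground-truth boxes (center format, same
#'   units); vectorized over paired rows.
#' @return angle cost values in `[0, 1]`.
#' @export
angle_cost <- function(pred, gt) {
  pred <- as_bbox(pred); gt <- as_bbox(gt)
  dx <- gt[, "cx"] - pred[, "cx"]
  dy <- gt[, "cy"] - pred[, "cy"]
  s2 <- dx^2 + dy^2
  unname(ifelse(s2 <= .siou_eps^2, 0, 2 * abs(dy) * abs(dx) / s2))
}

#' Distance cost of the SIoU loss
#'
#' \eqn{\Delta = (1 - e^{-\gamma p_x}) + (1 - e^{-\gamma p_y})} with
#' \eqn{p_x = ((b^{gt}_{cx} - b_{cx}) / c_w)^2}, \eqn{p_y} analogous,
#' where \eqn{c_w, c_h} are the width and height of the minimum rectangle
#' enclosing both boxes and \eqn{\gamma = 2 - \Lambda} couples the cost to
#' the angle term: the closer the centers are to a 45-degree arrangement,
#' the milder the distance penalty.  A zero-size enclosing rectangle
#' (identical degenerate boxes) yields 0 by convention.
#'
#' @inheritParams angle_cost
#' @param angle precomputed angle cost \eqn{\Lambda}; computed from the
#'   boxes when omitted.
#' @return distance cost values in `[0, 2]`.
#' @export
distance_cost <- function(pred, gt, angle = NULL) {
  pred <- as_bbox(pred); gt <- as_bbox(gt)
  if (is.null(angle)) angle <- angle_cost(pred, gt)
  cp <- bbox_to_corners(pred); cg <- bbox_to_corners(gt)
  cw <- pmax(cp[, "x2"], cg[, "x2"]) - pmin(cp[, "x1"], cg[, "x1"])
  ch <- pmax(cp[, "y2"], cg[, "y2"]) - pmin(cp[, "y1"], cg[, "y1"])
  px <- ifelse(cw <= .siou_eps, 0, ((gt[, "cx"] - pred[, "cx"]) / cw)^2)
  py <- ifelse(ch <= .siou_eps, 0, ((gt[, "cy"] - pred[, "cy"]) / ch)^2)
  gam <- 2 - angle
  unname((1 - exp(-gam * px)) + (1 - exp(-gam * py)))
}

#' Shape cost of the SIoU loss
#'
#' \eqn{\Omega = (1 - e^{-w_w})^\theta + (1 - e^{-w_h})^\theta} with
#' \eqn{w_w = |w - w^{gt}| / \max(w, w^{gt})} and \eqn{w_h} analogous.
#' Larger `theta` focuses the penalty on gross shape mismatch and relaxes
#' it for near-matching shapes.
#'
#' @inheritParams angle_cost
#' @param params SIoU parameters, see [siou_params()].
#' @return shape cost values in `[0, 2]`.
#' @export
shape_cost <- function(pred, gt, params = siou_params()) {
  pred <- as_bbox(pred); gt <- as_bbox(gt)
  ww <- abs(pred[, "w"] - gt[, "w"]) / pmax(pred[, "w"], gt[, "w"])
  wh <- abs(pred[, "h"] - gt[, "h"]) / pmax(pred[, "h"], gt[, "h"])
  unname((1 - exp(-ww))^params$theta + (1 - exp(-wh))^params$theta)
}

#' All SIoU cost terms for box pairs
#'
#' Returns the intermediate quantities of the SIoU decomposition for
#' inspection and testing: IoU, angle/distance/shape costs, the center
#' distance `sigma`, the vertical center gap `ch`, the enclosing-rectangle
#' dimensions and `gamma = 2 - angle_cost`.
#'
#' @inheritParams shape_cost
#' @return a data frame with one row per box pair.
#' @export
siou_terms <- function(pred, gt, params = siou_params()) {
  pred <- as_bbox(pred); gt <- as_bbox(gt)
  dx <- gt[, "cx"] - pred[, "cx"]
  dy <- gt[, "cy"] - pred[, "cy"]
  cp <- bbox_to_corners(pred); cg <- bbox_to_corners(gt)
  lam <- angle_cost(pred, gt)
  data.frame(
    iou = box_iou(pred, gt),
    angle_cost = lam,
    distance_cost = distance_cost(pred, gt, lam),
    shape_cost = shape_cost(pred, gt, params),
    sigma = sqrt(dx^2 + dy^2),
    ch = abs(dy),
    cw_enclose = pmax(cp[, "x2"], cg[, "x2"]) - pmin(cp[, "x1"], cg[, "x1"]),
    ch_enclose = pmax(cp[, "y2"], cg[, "y2"]) - pmin(cp[, "y1"], cg[, "y1"]),
    gamma = 2 - lam
  )
}

#' SIoU bounding-box regression loss
#'
#' \eqn{L_{BOX} = 1 - IoU + (\Delta + \Omega)/2}.  Zero exactly for
#' identical boxes; bounded above by 3.
#'
#' @inheritParams shape_cost
#' @return loss values, one per box pair.
#' @export
siou_box_loss <- function(pred, gt, params = siou_params()) {
  pred <- as_bbox(pred); gt <- as_bbox(gt)
  lam <- angle_cost(pred, gt)
  1 - box_iou(pred, gt) +
    (distance_cost(pred, gt, lam) + shape_cost(pred, gt, params)) / 2
}

#' Gradient of the SIoU loss in the predicted box parameters
#'
#' Central finite differences of [siou_box_loss()] in each of the four
#' predicted-box parameters, vectorized over box pairs.  The step is
#' scaled to the box size so pixel- and normalized-unit boxes are handled
#' alike.  Used by the training loop; exactness against the analytic IoU
#' path is covered by the test suite.
#'
#' @inheritParams shape_cost
#' @param rel_step relative step size for the differences.
#' @return an n-by-4 matrix of partial derivatives with columns
#'   `cx`, `cy`, `w`, `h`.
#' @export
siou_box_grad <- function(pred, gt, params = siou_params(),
                          rel_step = 1e-4) {
  pred <- as_bbox(pred); gt <- as_bbox(gt)
  scale <- pmax(pred[, "w"], pred[, "h"], gt[, "w"], gt[, "h"])
  h <- rel_step * scale
  g <- matrix(0, nrow(pred), 4L,
              dimnames = list(NULL, c("cx", "cy", "w", "h")))
  for (j in 1:4) {
    hi <- lo <- pred
    hi[, j] <- hi[, j] + h
    lo[, j] <- lo[, j] - h
    if (j >= 3) {  # keep width/height positive under perturbation
      lo[, j] <- pmax(lo[, j], .siou_eps)
      g[, j] <- (siou_box_loss(hi, gt, params) -
                 siou_box_loss(lo, gt, params)) / (hi[, j] - lo[, j])
    } else {
      g[, j] <- (siou_box_loss(hi, gt, params) -
                 siou_box_loss(lo, gt, params)) / (2 * h)
    }
  }
  g
}
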