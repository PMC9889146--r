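#' Confusion counts
#'
#' @param tp,fp,tn,fn non-negative integer counts: true/false positives
#'   and negatives.
#' @return a list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0, fp = 0, tn = 0, fn = 0) {
  cts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (anyNA(cts) || any(cts < 0) || any(cts != round(cts)))
    stop("confusion counts must be non-negative integers")
  structure(as.list(cts), class = "confusion_counts")
}

.rate <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); reported as NA")
    return(NA_real_)
  }
  num / den
}

#' Classification rates from confusion counts
#'
#' `precision` is TP/(TP+FP) — the positive predictive value (PPV);
#' `recall` is TP/(TP+FN) — the sensitivity (S); `specificity` is
#' TN/(TN+FP); `accuracy` is (TP+TN)/(TP+FP+TN+FN).  A zero denominator
#' yields `NA` with a warning rather than a silent 0.
#'
#' @param counts a [confusion_counts()] object.
#' @return a rate in `[0, 1]`, or `NA` when undefined.
#' @export
precision <- function(counts) {
  .rate(counts$tp, counts$tp + counts$fp, "precision")
}

#' @rdname precision
#' @export
recall <- function(counts) {
  .rate(counts$tp, counts$tp + counts$fn, "recall")
}

#' @rdname precision
#' @export
specificity <- function(counts) {
  .rate(counts$tn, counts$tn + counts$fp, "specificity")
}

#' @rdname precision
#' @export
accuracy <- function(counts) {
  .rate(counts$tp + counts$tn,
        counts$tp + counts$fp + counts$tn + counts$fn, "accuracy")
}

#' F1 score
#'
#' Harmonic combination \eqn{F_1 = 2PR/(P+R)} of precision and recall.
#' `P = R = 0` is defined as 0 (with a warning); the score always lies
#' between `min(P, R)` and `max(P, R)` with equality iff `P = R`.
#'
#' @param precision_value,recall_value rates in `[0, 1]`.
#' @return the F1 score.
#' @export
f1 <- function(precision_value, recall_value) {
  if (anyNA(c(precision_value, recall_value))) return(NA_real_)
  if (precision_value + recall_value == 0) {
    warning("F1 undefined at P = R = 0; reported as 0")
    return(0)
  }
  2 * precision_value * recall_value / (precision_value + recall_value)
}

#' Average precision of a ranked detection list
#'
#' Detections are matched to ground-truth boxes greedily in descending
#' score order: each detection claims the unmatched ground-truth box of
#' the same image with the highest IoU, provided that IoU reaches
#' `iou_match_threshold`; otherwise it counts as a false positive.  AP is
#' the exact area under the resulting precision-recall curve with the
#' precision envelope (all-point interpolation).
#'
#' @param detections data frame with columns `image`, `score`, and box
#'   columns `cx`, `cy`, `w`, `h` (single class; filter beforehand).
#' @param gt data frame of ground-truth boxes with columns `image`,
#'   `cx`, `cy`, `w`, `h`.
#' @param iou_match_threshold minimum IoU for a detection to match.
#' @return the average precision in `[0, 1]`; `NA` with a warning when
#'   there is no ground truth for the class.
#' @export
average_precision <- function(detections, gt, iou_match_threshold = 0.5) {
  gt <- as.data.frame(gt)
  n_gt <- nrow(gt)
  if (n_gt == 0L) {
    warning("no ground truth for class; AP undefined")
    return(NA_real_)
  }
  detections <- as.data.frame(detections)
  if (nrow(detections) == 0L) return(0)
  detections <- detections[order(-detections$score), , drop = FALSE]
  gt_used <- rep(FALSE, n_gt)
  tp <- logical(nrow(detections))
  for (i in seq_len(nrow(detections))) {
    cand <- which(gt$image == detections$image[i] & !gt_used)
    if (!length(cand)) next
    ious <- box_iou(detections[i, c("cx", "cy", "w", "h")],
                    gt[cand, c("cx", "cy", "w", "h")])
    j <- which.max(ious)
    if (ious[j] >= iou_match_threshold) {
      tp[i] <- TRUE
      gt_used[cand[j]] <- TRUE
    }
  }
  cum_tp <- cumsum(tp)
  rec <- cum_tp / n_gt
  prec <- cum_tp / seq_along(tp)
  # precision envelope, exact area under the PR curve
  prec_env <- rev(cummax(rev(prec)))
  sum(diff(c(0, rec)) * prec_env)
}

#' Mean average precision
#'
#' Arithmetic mean \eqn{mAP = \sum_i AP_i / k} over the `k` classes with
#' defined AP; `NA` entries (classes without ground truth) are excluded
#' with a warning.
#'
#' @param aps numeric vector of per-class average precisions.
#' @return the mean average precision.
#' @export
mean_average_precision <- function(aps) {
  if (length(aps) == 0L) stop("mean_average_precision needs at least one AP")
  if (anyNA(aps)) {
    warning(sum(is.na(aps)), " undefined AP value(s) excluded from mAP")
    aps <- aps[!is.na(aps)]
    if (!length(aps)) stop("all AP values undefined")
  }
  mean(aps)
}

#' McNemar test on paired correct/incorrect outcomes
#'
#' Compares two raters (or models) scored on the same cases against a
#' reference.  Only discordant pairs enter: `b` cases where A is correct
#' and B is not, `c` the reverse.  The reported statistic is the
#' continuity-corrected chi-square
#' \eqn{\chi^2 = (\max(|b-c|-1, 0))^2/(b+c)} on 1 df (0 when `b = c`,
#' including `b + c = 0`).  The p-value comes from that statistic when
#' `b + c >= 25`; for smaller discordant counts the asymptotic
#' approximation is poor and the exact two-sided binomial test of `b`
#' successes in `b + c` trials at p = 1/2 is used instead.
#'
#' @param correct_a,correct_b logical vectors: whether each rater was
#'   correct on each case (same case order).
#' @param b,c alternatively, the discordant counts directly.
#' @return a list with `b`, `c`, `statistic`, `p_value`, `method`, and
#'   `significant` (at `P < 0.05`).
#' @export
mcnemar_test <- function(correct_a = NULL, correct_b = NULL,
                         b = NULL, c = NULL) {
  if (is.null(b) || is.null(c)) {
    if (length(correct_a) != length(correct_b))
      stop("raters must be scored on the same cases")
    b <- sum(correct_a & !correct_b)
    c <- sum(!correct_a & correct_b)
  }
  if (b < 0 || c < 0) stop("discordant counts must be non-negative")
  n_disc <- b + c
  stat <- if (n_disc == 0) 0 else max(abs(b - c) - 1, 0)^2 / n_disc
  if (n_disc >= 25) {
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "mcnemar_chisq_corrected"
  } else if (n_disc == 0) {
    p <- 1
    method <- "mcnemar_chisq_corrected"
  } else {
    p <- stats::binom.test(b, n_disc, p = 0.5)$p.value
    method <- "exact_binomial"
  }
  list(b = b, c = c, statistic = stat, p_value = p, method = method,
       significant = p < 0.05)
}

#' Per-class detection evaluation report
#'
#' Computes, for each structure class, AP at the match threshold together
#' with PPV, sensitivity, F1 and specificity derived from the matched
#' confusion counts, plus aggregate rows.  Detections are matched to
#' ground truth exactly as in [average_precision()] but at the operating
#' score threshold: TP = matched detections, FP = unmatched detections,
#' FN = unmatched ground-truth boxes.  TN for a class is the number of
#' images containing neither a ground-truth box nor a detection of that
#' class (image-level absence agreement), which gives specificity a
#' defined denominator in a detection setting.
#'
#' @param detections data frame with columns `image`, `class`, `score`,
#'   `cx`, `cy`, `w`, `h`.
#' @param gt data frame with columns `image`, `class`, `cx`, `cy`, `w`, `h`.
#' @param classes class names to report (default: all classes present in
#'   the ground truth, in [structure_classes()] order).
#' @param iou_match_threshold IoU needed for a detection to match.
#' @param score_threshold operating confidence threshold for the
#'   PPV/S/F1/specificity columns (AP uses all detections).
#' @return a data frame of class `eval_report`: one row per class plus an
#'   `"All"` row of macro averages; columns `class`, `ap`, `ppv`,
#'   `sensitivity`, `f1`, `specificity`, `tp`, `fp`, `fn`, `tn`,
#'   `n_gt`.  Rates are fractions in `[0, 1]`.
#' @export
evaluate_detections <- function(detections, gt, classes = NULL,
                                iou_match_threshold = 0.5,
                                score_threshold = 0.25) {
  if (is.null(detections) || NROW(detections) == 0L)
    detections <- data.frame(image = character(), class = character(),
                             score = numeric(), cx = numeric(),
                             cy = numeric(), w = numeric(), h = numeric())
  detections <- as.data.frame(detections); gt <- as.data.frame(gt)
  if (is.null(classes)) {
    classes <- intersect(structure_classes(), unique(gt$class))
    if (!length(classes)) classes <- sort(unique(gt$class))
  }
  all_images <- unique(c(detections$image, gt$image))
  rows <- lapply(classes, function(cl) {
    det_c <- detections[detections$class == cl, , drop = FALSE]
    gt_c <- gt[gt$class == cl, , drop = FALSE]
    ap <- if (nrow(gt_c)) {
      average_precision(det_c, gt_c, iou_match_threshold)
    } else NA_real_
    det_op <- det_c[det_c$score >= score_threshold, , drop = FALSE]
    m <- match_detections(det_op, gt_c, iou_match_threshold)
    tp <- sum(m); fp <- nrow(det_op) - tp; fn <- nrow(gt_c) - tp
    neg_imgs <- setdiff(all_images, unique(gt_c$image))
    tn <- sum(!neg_imgs %in% det_op$image)
    cts <- confusion_counts(tp, fp, tn, fn)
    p <- suppressWarnings(precision(cts)); r <- suppressWarnings(recall(cts))
    data.frame(class = cl, ap = ap, ppv = p, sensitivity = r,
               f1 = suppressWarnings(f1(p, r)),
               specificity = suppressWarnings(specificity(cts)),
               tp = tp, fp = fp, fn = fn, tn = tn, n_gt = nrow(gt_c))
  })
  rep_df <- do.call(rbind, rows)
  all_row <- data.frame(
    class = "All",
    ap = suppressWarnings(mean_average_precision(rep_df$ap)),
    ppv = mean(rep_df$ppv, na.rm = TRUE),
    sensitivity = mean(rep_df$sensitivity, na.rm = TRUE),
    f1 = mean(rep_df$f1, na.rm = TRUE),
    specificity = mean(rep_df$specificity, na.rm = TRUE),
    tp = sum(rep_df$tp), fp = sum(rep_df$fp), fn = sum(rep_df$fn),
    tn = sum(rep_df$tn), n_gt = sum(rep_df$n_gt))
  out <- rbind(rep_df, all_row)
  class(out) <- c("eval_report", "data.frame")
  out
}

# Greedy one-to-one matching by descending score; returns a logical
# vector marking which detections matched a ground-truth box.
match_detections <- function(detections, gt, iou_match_threshold = 0.5) {
  if (nrow(detections) == 0L) return(logical(0))
  ord <- order(-detections$score)
  matched <- logical(nrow(detections))
  gt_used <- rep(FALSE, nrow(gt))
  for (i in ord) {
    cand <- which(gt$image == detections$image[i] & !gt_used)
    if (!length(cand)) next
    ious <- box_iou(detections[i, c("cx", "cy", "w", "h")],
                    gt[cand, c("cx", "cy", "w", "h")])
    j <- which.max(ious)
    if (ious[j] >= iou_match_threshold) {
      matched[i] <- TRUE
      gt_used[cand[j]] <- TRUE
    }
  }
  matched
}

#' Rater comparison report with McNemar tests
#'
#' Scores each rater's per-image section labels against reference labels,
#' section by section and overall, and tests each non-reference rater
#' against a baseline rater on paired correctness with [mcnemar_test()].
#' For a given section, a case is positive when the reference labels it
#' as that section; sensitivity, specificity, PPV and accuracy follow
#' from the induced one-vs-rest confusion counts.
#'
#' @param ratings a named list of character vectors of section labels
#'   (including `"NONSTANDARD"`), one per rater, all scored on the same
#'   cases in the same order.
#' @param reference character vector of reference section labels.
#' @param baseline name of the rater against which McNemar tests are run
#'   (default: the first rater).
#' @return a list of class `rater_comparison` with elements `metrics` (a
#'   data frame: rater, section, sensitivity, specificity, ppv, accuracy)
#'   and `mcnemar` (a data frame: rater, section, b, c, p_value,
#'   significant vs the baseline).
#' @export
rater_report <- function(ratings, reference, baseline = NULL) {
  if (!length(names(ratings)) || any(names(ratings) == ""))
    stop("ratings must be a named list of raters")
  n <- length(reference)
  if (any(lengths(ratings) != n))
    stop("all raters must score the same case set as the reference")
  if (is.null(baseline)) baseline <- names(ratings)[1L]
  if (!baseline %in% names(ratings)) stop("unknown baseline rater")
  sections <- unique(c(names(section_templates()), reference))
  sections <- sections[sections != "NONSTANDARD"]

  one_vs_rest <- function(pred, section) {
    pos <- reference == section
    hit <- pred == section
    confusion_counts(tp = sum(pos & hit), fp = sum(!pos & hit),
                     tn = sum(!pos & !hit), fn = sum(pos & !hit))
  }
  metrics <- do.call(rbind, lapply(names(ratings), function(r) {
    per_sec <- do.call(rbind, lapply(sections, function(s) {
      cts <- one_vs_rest(ratings[[r]], s)
      data.frame(rater = r, section = s,
                 sensitivity = suppressWarnings(recall(cts)),
                 specificity = suppressWarnings(specificity(cts)),
                 ppv = suppressWarnings(precision(cts)),
                 accuracy = suppressWarnings(accuracy(cts)))
    }))
    overall_correct <- ratings[[r]] == reference
    std_ref <- reference != "NONSTANDARD"
    std_pred <- ratings[[r]] == reference & std_ref
    cts <- confusion_counts(tp = sum(std_ref & std_pred),
                            fp = sum(!std_ref & ratings[[r]] != "NONSTANDARD"),
                            tn = sum(!std_ref & ratings[[r]] == "NONSTANDARD"),
                            fn = sum(std_ref & !std_pred))
    rbind(per_sec, data.frame(
      rater = r, section = "Whole",
      sensitivity = suppressWarnings(recall(cts)),
      specificity = suppressWarnings(specificity(cts)),
      ppv = suppressWarnings(precision(cts)),
      accuracy = mean(overall_correct)))
  }))

  others <- setdiff(names(ratings), baseline)
  mcn <- do.call(rbind, lapply(others, function(r) {
    per_sec <- do.call(rbind, lapply(c(sections, "Whole"), function(s) {
      idx <- if (s == "Whole") rep(TRUE, n) else reference == s
      ca <- (ratings[[r]] == reference)[idx]
      cb <- (ratings[[baseline]] == reference)[idx]
      t <- mcnemar_test(ca, cb)
      data.frame(rater = r, section = s, b = t$b, c = t$c,
                 p_value = t$p_value, significant = t$significant)
    }))
    per_sec
  }))
  structure(list(metrics = metrics, mcnemar = mcn, baseline = baseline),
            class = "rater_comparison")
}
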