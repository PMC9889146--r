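#' Assign ground-truth boxes to anchors and grid cells
#'
#' Positive-sample matching for the four-scale detector.  For every
#' ground-truth box and every scale, anchors pass a compatibility gate
#' when `max(w/aw, aw/w, h/ah, ah/h) < ratio_gate`; each passing
#' (scale, anchor) pair produces positives at the grid cell containing
#' the box center plus its two nearest neighbor cells (left/right and
#' up/down according to which side of the cell center the box center
#' falls), as permitted by the decoder's ±0.5-cell center range.  The
#' result is deterministic and invariant to the ordering of the
#' ground-truth rows: conflicts where two boxes claim the same
#' (scale, anchor, cell) slot are resolved in favor of the box whose
#' center is nearest the cell center, with a canonical coordinate sort
#' breaking exact ties.
#'
#' @param gt_boxes data frame with columns `class` (0-based integer id),
#'   `cx`, `cy`, `w`, `h` in input pixels.  Boxes reaching outside the
#'   image are clipped with a warning.
#' @param config a [model_config()].
#' @param ratio_gate anchor/box dimension ratio limit.
#' @return a data frame of positive matches with columns `scale`,
#'   `anchor`, `gi` (0-based column), `gj` (0-based row), `gt` (row index
#'   into `gt_boxes`), `class`, `cx`, `cy`, `w`, `h`; zero rows when
#'   `gt_boxes` is empty.
#' @export
assign_targets <- function(gt_boxes, config, ratio_gate = 4) {
  empty <- data.frame(scale = integer(), anchor = integer(), gi = integer(),
                      gj = integer(), gt = integer(), class = integer(),
                      cx = numeric(), cy = numeric(), w = numeric(),
                      h = numeric())
  gt_boxes <- as.data.frame(gt_boxes)
  if (nrow(gt_boxes) == 0L) return(empty)
  size <- config$input_size
  co <- bbox_to_corners(gt_boxes[, c("cx", "cy", "w", "h")])
  if (any(co < 0) || any(co > size)) {
    warning("ground-truth box outside the image; clipping")
    b <- clip_boxes(gt_boxes[, c("cx", "cy", "w", "h")], size, size)
    gt_boxes <- gt_boxes[attr(b, "kept"), , drop = FALSE]
    gt_boxes[, c("cx", "cy", "w", "h")] <- b
    if (nrow(gt_boxes) == 0L) return(empty)
  }
  rows <- list()
  for (s in seq_along(config$strides)) {
    stride <- config$strides[s]
    g <- size %/% stride
    anchors <- config$anchors[[s]]
    for (a in seq_len(nrow(anchors))) {
      r <- pmax(gt_boxes$w / anchors[a, "w"], anchors[a, "w"] / gt_boxes$w,
                gt_boxes$h / anchors[a, "h"], anchors[a, "h"] / gt_boxes$h)
      ok <- which(r < ratio_gate)
      for (i in ok) {
        fx <- gt_boxes$cx[i] / stride
        fy <- gt_boxes$cy[i] / stride
        gi0 <- min(max(floor(fx), 0), g - 1L)
        gj0 <- min(max(floor(fy), 0), g - 1L)
        dgi <- if (fx - gi0 < 0.5) -1L else 1L
        dgj <- if (fy - gj0 < 0.5) -1L else 1L
        cells <- rbind(c(gi0, gj0), c(gi0 + dgi, gj0), c(gi0, gj0 + dgj))
        cells <- cells[cells[, 1] >= 0 & cells[, 1] < g &
                       cells[, 2] >= 0 & cells[, 2] < g, , drop = FALSE]
        rows[[length(rows) + 1L]] <- data.frame(
          scale = s, anchor = a, gi = cells[, 1], gj = cells[, 2], gt = i,
          class = gt_boxes$class[i], cx = gt_boxes$cx[i],
          cy = gt_boxes$cy[i], w = gt_boxes$w[i], h = gt_boxes$h[i])
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  # order-invariant conflict resolution for shared (scale, anchor, cell)
  stride_of <- config$strides[out$scale]
  dist <- (out$cx / stride_of - (out$gi + 0.5))^2 +
          (out$cy / stride_of - (out$gj + 0.5))^2
  key <- paste(out$scale, out$anchor, out$gi, out$gj)
  ord <- order(key, dist, out$cx, out$cy, out$w, out$h, out$class)
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(key[ord]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
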