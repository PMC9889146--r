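# Independent reference implementations used to cross-check the package's
# fast paths, plus small fixture builders.  Oracles are deliberately naive.

# Counting oracle for IoU: pixel centers of an integer grid.
raster_iou <- function(a, b, extent = 40L) {
  px <- rep(seq_len(extent) - 0.5, times = extent)
  py <- rep(seq_len(extent) - 0.5, each = extent)
  inside <- function(box) {
    px >= box[1] - box[3] / 2 & px <= box[1] + box[3] / 2 &
    py >= box[2] - box[4] / 2 & py <= box[2] + box[4] / 2
  }
  ia <- inside(a); ib <- inside(b)
  inter <- sum(ia & ib); uni <- sum(ia | ib)
  if (uni == 0) 0 else inter / uni
}

# Boxes with integer corners inside the oracle grid, so rasterization is exact.
random_int_boxes <- function(n, max_side = 12L, origin_max = 24L) {
  w <- sample.int(max_side, n, replace = TRUE)
  h <- sample.int(max_side, n, replace = TRUE)
  x1 <- sample.int(origin_max, n, replace = TRUE)
  y1 <- sample.int(origin_max, n, replace = TRUE)
  bbox(cx = x1 + w / 2, cy = y1 + h / 2, w = w, h = h)
}

# Naive greedy NMS, one box at a time, no vectorization.
nms_oracle <- function(det, iou_thr, score_thr) {
  det <- det[det$score >= score_thr, , drop = FALSE]
  det <- det[order(-det$score), , drop = FALSE]
  kept <- det[0, ]
  for (i in seq_len(nrow(det))) {
    ok <- TRUE
    for (j in seq_len(nrow(kept))) {
      if (kept$class[j] != det$class[i]) next
      iou <- box_iou(as_bbox(det[i, c("cx", "cy", "w", "h")]),
                     as_bbox(kept[j, c("cx", "cy", "w", "h")]))
      if (iou > iou_thr) { ok <- FALSE; break }
    }
    if (ok) kept <- rbind(kept, det[i, ])
  }
  rownames(kept) <- NULL
  kept
}

# All-point AP by direct enumeration of the PR curve from a TP/FP flag
# sequence (already ranked by score) and a ground-truth count.
ap_from_flags <- function(tp_flags, n_gt) {
  ap <- 0
  prev_rec <- 0
  for (k in seq_along(tp_flags)) {
    rec <- sum(tp_flags[1:k]) / n_gt
    if (rec > prev_rec) {
      # precision envelope: best precision at any cutoff with recall >= rec
      best <- 0
      for (m in k:length(tp_flags)) {
        best <- max(best, sum(tp_flags[1:m]) / m)
      }
      ap <- ap + (rec - prev_rec) * best
      prev_rec <- rec
    }
  }
  ap
}

# Reference section rule: largest fully satisfied template, ties by the
# documented priority order; NONSTANDARD when none is complete.
section_oracle <- function(present) {
  templates <- section_templates()
  prio <- c("4CH", "3VT", "LVOT", "RVOT", "3VV")
  complete <- names(templates)[vapply(templates, function(req)
    all(req %in% present), logical(1))]
  if (!length(complete)) return("NONSTANDARD")
  sizes <- lengths(templates[complete])
  best <- complete[sizes == max(sizes)]
  best[order(match(best, prio))][1]
}

# Small annotated training fixture: one easy section image replicated.
fixture_single_image_set <- function(section = "3VT", size = 128L,
                                     seed = 5L, n = 8L) {
  a <- generate_image(scene_spec(section, size = size), seed = seed)
  b <- a$boxes[, c("class", "cx", "cy", "w", "h")]
  b$class <- a$boxes$class_id
  list(annotated = a,
       dataset = list(images = rep(list(a$image), n),
                      boxes = rep(list(b), n)))
}
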