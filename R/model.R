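#' Detector configuration
#'
#' Describes a four-scale anchor-based single-stage detector: a CSPDarknet
#' backbone (focus stem, conv+BN+SiLU blocks, CSP1/CSP2 stages, SPP) with
#' an FPN+PAN neck and one detection head per scale.  Detection grids live
#' at 1/8, 1/16, 1/32 and 1/64 of the input resolution so small vessels
#' and the large four-chamber region are handled at different scales.
#'
#' @param input_size square input side in pixels; must be divisible by the
#'   largest stride (64 by default).
#' @param depth_multiple scaling of the bottleneck counts in CSP blocks.
#' @param width_multiple channel-width scaling of the full-size network.
#' @param num_classes number of anatomical structure classes.
#' @param strides detection-scale downsampling factors.
#' @param anchors list (one element per scale) of `n_anchor x 2` matrices
#'   of (w, h) priors in pixels; `NULL` for built-in fallback priors (use
#'   [kmeans_anchors()] to fit dataset-specific priors).
#' @param spp_kernels SPP max-pool window sizes (odd).
#' @param in_channels input image channels (1 for grayscale ultrasound).
#' @return a list of class `model_config`.
#' @export
model_config <- function(input_size = 128, depth_multiple = 0.33,
                         width_multiple = 0.25, num_classes = 10,
                         strides = c(8L, 16L, 32L, 64L), anchors = NULL,
                         spp_kernels = c(3L, 5L, 7L), in_channels = 1L) {
  if (input_size %% max(strides) != 0)
    stop("input_size must be divisible by the largest stride (",
         max(strides), ")")
  if (length(strides) != 4L) stop("the detector uses exactly four scales")
  if (any(spp_kernels %% 2 == 0)) stop("spp_kernels must be odd")
  if (is.null(anchors)) anchors <- default_anchors(input_size, strides)
  if (length(anchors) != length(strides))
    stop("anchors must provide one matrix per scale")
  anchors <- lapply(anchors, function(a) {
    a <- matrix(as.numeric(a), ncol = 2)
    colnames(a) <- c("w", "h")
    a
  })
  structure(list(input_size = as.integer(input_size),
                 depth_multiple = depth_multiple,
                 width_multiple = width_multiple,
                 num_classes = as.integer(num_classes),
                 strides = as.integer(strides), anchors = anchors,
                 spp_kernels = as.integer(spp_kernels),
                 in_channels = as.integer(in_channels)),
            class = "model_config")
}

# Fallback anchor priors: per scale, boxes around 2x-5x the stride,
# covering squat / square / tall aspects.
default_anchors <- function(input_size, strides) {
  lapply(strides, function(s) {
    cbind(w = c(2.5, 4, 3) * s, h = c(2.5, 3, 4.5) * s)
  })
}

#' Fit anchor priors to a dataset by k-means
#'
#' Clusters the ground-truth box dimensions into `3 * n_scales` priors and
#' distributes them to the detection scales by ascending area.
#'
#' @param boxes matrix/data frame with columns `w`, `h` in input pixels.
#' @param config a [model_config()].
#' @param per_scale number of anchors per scale.
#' @param seed RNG seed for the k-means initialization.
#' @return an anchors list usable in [model_config()].
#' @export
kmeans_anchors <- function(boxes, config, per_scale = 3L, seed = 1L) {
  wh <- as.matrix(as.data.frame(boxes)[, c("w", "h")])
  k <- per_scale * length(config$strides)
  if (nrow(wh) < k)
    stop("need at least ", k, " boxes to fit anchors")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  km <- stats::kmeans(wh, centers = k, nstart = 5, iter.max = 50)
  cen <- km$centers[order(km$centers[, 1] * km$centers[, 2]), , drop = FALSE]
  lapply(seq_along(config$strides), function(i) {
    a <- cen[(i - 1L) * per_scale + seq_len(per_scale), , drop = FALSE]
    colnames(a) <- c("w", "h")
    a
  })
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}

.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

ch_width <- function(base, wm) max(4L, as.integer(2 * round(base * wm / 2)))

n_bottlenecks <- function(base, dm) max(1L, as.integer(round(base * dm)))

# conv + batch-norm + SiLU, the CBS block
add_cbs <- function(net, name, from, cin, cout, k = 3L, stride = 1L) {
  nn_add(net, paste0(name, "_conv"), "conv", from,
         cin = cin, cout = cout, k = k, stride = stride, bias = FALSE)
  nn_add(net, paste0(name, "_bn"), "bn", paste0(name, "_conv"), c = cout)
  nn_add(net, name, "silu", paste0(name, "_bn"))
  invisible(net)
}

# Cross-stage-partial block: split into a bottleneck branch and a bypass
# branch, concatenate and mix.  shortcut = TRUE gives the residual CSP1
# variant used in the backbone, FALSE the CSP2 variant of the neck.
add_csp <- function(net, name, from, cin, cout, n, shortcut = TRUE) {
  ch <- max(4L, cout %/% 2L)
  add_cbs(net, paste0(name, "_cv1"), from, cin, ch, k = 1L)
  add_cbs(net, paste0(name, "_cv2"), from, cin, ch, k = 1L)
  prev <- paste0(name, "_cv1")
  for (i in seq_len(n)) {
    b <- paste0(name, "_b", i)
    add_cbs(net, paste0(b, "_1"), prev, ch, ch, k = 1L)
    add_cbs(net, paste0(b, "_2"), paste0(b, "_1"), ch, ch, k = 3L)
    if (shortcut) {
      nn_add(net, b, "add", c(paste0(b, "_2"), prev))
    } else {
      nn_add(net, b, "identity", paste0(b, "_2"))
    }
    prev <- b
  }
  nn_add(net, paste0(name, "_cat"), "concat", c(prev, paste0(name, "_cv2")))
  add_cbs(net, name, paste0(name, "_cat"), 2L * ch, cout, k = 1L)
  invisible(net)
}

# Spatial pyramid pooling with parallel same-size max pools.
add_spp <- function(net, name, from, cin, cout, kernels) {
  ch <- max(4L, cin %/% 2L)
  add_cbs(net, paste0(name, "_cv1"), from, cin, ch, k = 1L)
  pools <- character()
  for (k in kernels) {
    p <- paste0(name, "_p", k)
    nn_add(net, p, "maxpool", paste0(name, "_cv1"), k = as.integer(k))
    pools <- c(pools, p)
  }
  nn_add(net, paste0(name, "_cat"), "concat", c(paste0(name, "_cv1"), pools))
  add_cbs(net, name, paste0(name, "_cat"),
          ch * (1L + length(kernels)), cout, k = 1L)
  invisible(net)
}

#' Build the four-scale single-stage detector
#'
#' Assembles the full graph: focus stem; CSPDarknet backbone with CSP1
#' stages at strides 8/16/32 and an SPP + CSP2 stage at stride 64; an
#' FPN top-down path fusing upsampled deep features with shallower ones
#' and a PAN bottom-up path re-aggregating localization detail; and one
#' 1x1-convolution head per scale emitting, for each anchor and grid
#' cell, 4 box offsets, an objectness logit and `num_classes` class
#' logits.
#'
#' @param config a [model_config()].
#' @param seed seed for weight initialization.
#' @return a list of class `detector` with elements `net` (the graph),
#'   `config` and `head_names`.
#' @export
build_model <- function(config, seed = 0L) {
  stopifnot(inherits(config, "model_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  wm <- config$width_multiple; dm <- config$depth_multiple
  c1 <- ch_width(64, wm); c2 <- ch_width(128, wm); c3 <- ch_width(256, wm)
  c4 <- ch_width(512, wm); c5 <- ch_width(768, wm); c6 <- ch_width(1024, wm)
  n1 <- n_bottlenecks(3, dm); n2 <- n_bottlenecks(6, dm)

  net <- nn_network()
  nn_add(net, "input", "input")
  nn_add(net, "focus", "focus", "input")
  add_cbs(net, "stem", "focus", 4L * config$in_channels, c1, k = 3L)
  add_cbs(net, "d2", "stem", c1, c2, k = 3L, stride = 2L)
  add_csp(net, "b2", "d2", c2, c2, n1, shortcut = TRUE)
  add_cbs(net, "d3", "b2", c2, c3, k = 3L, stride = 2L)
  add_csp(net, "b3", "d3", c3, c3, n2, shortcut = TRUE)          # stride 8
  add_cbs(net, "d4", "b3", c3, c4, k = 3L, stride = 2L)
  add_csp(net, "b4", "d4", c4, c4, n2, shortcut = TRUE)          # stride 16
  add_cbs(net, "d5", "b4", c4, c5, k = 3L, stride = 2L)
  add_csp(net, "b5", "d5", c5, c5, n1, shortcut = TRUE)          # stride 32
  add_cbs(net, "d6", "b5", c5, c6, k = 3L, stride = 2L)
  add_spp(net, "spp", "d6", c6, c6, config$spp_kernels)          # stride 64
  add_csp(net, "b6", "spp", c6, c6, n1, shortcut = FALSE)

  # FPN: top-down
  add_cbs(net, "lat6", "b6", c6, c5, k = 1L)
  nn_add(net, "up6", "upsample", "lat6")
  nn_add(net, "cat5", "concat", c("up6", "b5"))
  add_csp(net, "n5", "cat5", 2L * c5, c5, n1, shortcut = FALSE)
  add_cbs(net, "lat5", "n5", c5, c4, k = 1L)
  nn_add(net, "up5", "upsample", "lat5")
  nn_add(net, "cat4", "concat", c("up5", "b4"))
  add_csp(net, "n4", "cat4", 2L * c4, c4, n1, shortcut = FALSE)
  add_cbs(net, "lat4", "n4", c4, c3, k = 1L)
  nn_add(net, "up4", "upsample", "lat4")
  nn_add(net, "cat3", "concat", c("up4", "b3"))
  add_csp(net, "p3", "cat3", 2L * c3, c3, n1, shortcut = FALSE)

  # PAN: bottom-up
  add_cbs(net, "pd3", "p3", c3, c3, k = 3L, stride = 2L)
  nn_add(net, "catp4", "concat", c("pd3", "lat4"))
  add_csp(net, "p4", "catp4", 2L * c3, c4, n1, shortcut = FALSE)
  add_cbs(net, "pd4", "p4", c4, c4, k = 3L, stride = 2L)
  nn_add(net, "catp5", "concat", c("pd4", "lat5"))
  add_csp(net, "p5", "catp5", 2L * c4, c5, n1, shortcut = FALSE)
  add_cbs(net, "pd5", "p5", c5, c5, k = 3L, stride = 2L)
  nn_add(net, "catp6", "concat", c("pd5", "lat6"))
  add_csp(net, "p6", "catp6", 2L * c5, c6, n1, shortcut = FALSE)

  na <- nrow(config$anchors[[1]])
  cout_head <- na * (5L + config$num_classes)
  head_names <- character(4)
  for (i in 1:4) {
    src <- c("p3", "p4", "p5", "p6")[i]
    cin <- c(c3, c4, c5, c6)[i]
    h <- paste0("head", i)
    nn_add(net, h, "conv", src, cin = cin, cout = cout_head, k = 1L,
           bias = TRUE)
    # objectness prior ~1%: keeps early training from drowning in negatives
    b <- numeric(cout_head)
    per <- 5L + config$num_classes
    b[rep(seq(0L, (na - 1L) * per, per), each = 1L) + 5L] <- -4.6
    net$nodes[[h]]$b <- b
    head_names[i] <- h
  }
  net$heads <- head_names
  structure(list(net = net, config = config, head_names = head_names),
            class = "detector")
}

#' @export
print.detector <- function(x, ...) {
  cat(sprintf(
    "four-scale single-stage detector: input %dpx, %d classes, %s params%s\n",
    x$config$input_size, x$config$num_classes,
    format(nn_count_params(x$net), big.mark = ","),
    if (x$net$fused) " (conv+BN fused)" else ""))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Head codec: raw per-cell offsets <-> pixel boxes.
# bx = (2*sigmoid(tx) - 0.5 + gx) * stride   (gx 0-based grid column)
# bw = (2*sigmoid(tw))^2 * anchor_w
# ---------------------------------------------------------------------------

#' Decode raw head offsets to pixel boxes
#'
#' @param t matrix with columns `tx`, `ty`, `tw`, `th`.
#' @param gx,gy 0-based grid cell column/row indices.
#' @param anchor_w,anchor_h anchor dimensions in pixels.
#' @param stride scale stride in pixels.
#' @return a box matrix in input-pixel center format.
#' @export
decode_boxes <- function(t, gx, gy, anchor_w, anchor_h, stride) {
  t <- matrix(t, ncol = 4)
  cbind(cx = (2 * sigmoid(t[, 1]) - 0.5 + gx) * stride,
        cy = (2 * sigmoid(t[, 2]) - 0.5 + gy) * stride,
        w = (2 * sigmoid(t[, 3]))^2 * anchor_w,
        h = (2 * sigmoid(t[, 4]))^2 * anchor_h)
}

#' @rdname decode_boxes
#' @param boxes pixel boxes to encode (center format).
#' @export
encode_boxes <- function(boxes, gx, gy, anchor_w, anchor_h, stride) {
  boxes <- as_bbox(boxes)
  logit <- function(p) log(p / (1 - p))
  fx <- (boxes[, "cx"] / stride - gx + 0.5) / 2
  fy <- (boxes[, "cy"] / stride - gy + 0.5) / 2
  fw <- sqrt(boxes[, "w"] / anchor_w) / 2
  fh <- sqrt(boxes[, "h"] / anchor_h) / 2
  f <- cbind(fx, fy, fw, fh)
  if (any(f <= 0 | f >= 1))
    stop("box not representable at this cell/anchor (offset out of range)")
  cbind(tx = logit(fx), ty = logit(fy), tw = logit(fw), th = logit(fh))
}

# Chain rule factors d(box)/d(t) for the decoder above.
decode_grad_factors <- function(t, anchor_w, anchor_h, stride) {
  t <- matrix(t, ncol = 4)
  s <- sigmoid(t)
  cbind(cx = 2 * s[, 1] * (1 - s[, 1]) * stride,
        cy = 2 * s[, 2] * (1 - s[, 2]) * stride,
        w = 8 * s[, 3]^2 * (1 - s[, 3]) * anchor_w,
        h = 8 * s[, 4]^2 * (1 - s[, 4]) * anchor_h)
}

#' Greedy per-class non-maximum suppression
#'
#' Detections are processed per class in descending score order; a
#' detection is suppressed when its IoU with an already-kept detection of
#' the same class exceeds `iou_threshold`.  Survivors are returned sorted
#' by score.
#'
#' @param detections data frame with columns `class`, `score`, `cx`,
#'   `cy`, `w`, `h`.
#' @param iou_threshold suppression IoU in `[0, 1]`.
#' @param score_threshold minimum score to consider.
#' @return the filtered detection data frame.
#' @export
nms <- function(detections, iou_threshold = 0.45, score_threshold = 0.25) {
  if (iou_threshold < 0 || iou_threshold > 1 ||
      score_threshold < 0 || score_threshold > 1)
    stop("NMS thresholds must lie in [0, 1]")
  detections <- as.data.frame(detections)
  detections <- detections[detections$score >= score_threshold, , drop = FALSE]
  if (nrow(detections) == 0L) return(detections)
  detections <- detections[order(-detections$score), , drop = FALSE]
  keep <- logical(nrow(detections))
  for (cl in unique(detections$class)) {
    idx <- which(detections$class == cl)
    boxes <- as_bbox(detections[idx, c("cx", "cy", "w", "h")])
    taken <- integer()
    for (i in seq_along(idx)) {
      if (length(taken)) {
        ious <- box_iou(boxes[i, , drop = FALSE],
                        boxes[taken, , drop = FALSE])
        if (any(ious > iou_threshold)) next
      }
      taken <- c(taken, i)
      keep[idx[i]] <- TRUE
    }
  }
  out <- detections[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Letterbox a grayscale matrix (rows = y) to size x size, preserving
# aspect; returns the (C,H,W,1) tensor plus the mapping back to source
# pixels.
letterbox <- function(img, size, fill = 0.5) {
  h <- nrow(img); w <- ncol(img)
  r <- min(size / h, size / w)
  nh <- as.integer(round(h * r)); nw <- as.integer(round(w * r))
  resized <- if (nh == h && nw == w) img else {
    # EBImage uses (x, y) indexing; transpose in and out
    t(EBImage::resize(t(img), w = nw, h = nh))
  }
  top <- (size - nh) %/% 2L; left <- (size - nw) %/% 2L
  canvas <- matrix(fill, size, size)
  canvas[top + seq_len(nh), left + seq_len(nw)] <- resized
  list(tensor = array(canvas, c(1L, size, size, 1L)),
       scale = r, top = top, left = left)
}

#' Detect structures in a single image
#'
#' Letterboxes the image to the model input size, runs the network in
#' inference mode, decodes all anchor/cell predictions, scores them as
#' objectness times best class probability, and applies per-class NMS.
#' Box coordinates are mapped back to the original image and clipped.
#'
#' @param model a [build_model()] detector (trained weights loaded).
#' @param image numeric matrix in `[0, 1]`, rows = image rows (grayscale).
#' @param score_threshold,iou_threshold NMS operating point.
#' @param class_names optional class-name vector (defaults to
#'   [structure_classes()] when the class count matches).
#' @return a data frame of detections: `class_id` (0-based), `class`,
#'   `score`, `cx`, `cy`, `w`, `h` in source-image pixels.
#' @export
predict_image <- function(model, image, score_threshold = 0.25,
                          iou_threshold = 0.45, class_names = NULL) {
  cfg <- model$config
  if (!is.matrix(image))
    stop("image must be a numeric matrix (single-channel grayscale)")
  if (is.null(class_names)) {
    class_names <- if (cfg$num_classes == length(structure_classes()))
      structure_classes() else as.character(seq_len(cfg$num_classes) - 1L)
  }
  lb <- letterbox(image, cfg$input_size)
  nn_set_mode(model$net, FALSE)
  heads <- nn_forward(model$net, lb$tensor, outputs = model$head_names,
                      retain = FALSE)
  raw <- decode_heads(heads, cfg, batch_index = 1L)
  raw$score <- sigmoid(raw$obj) * sigmoid(raw$cls_best)
  det <- data.frame(class = raw$class_id, score = raw$score,
                    cx = raw$cx, cy = raw$cy, w = raw$w, h = raw$h)
  det <- nms(det, iou_threshold, score_threshold)
  if (nrow(det)) {
    det$cx <- (det$cx - lb$left) / lb$scale
    det$cy <- (det$cy - lb$top) / lb$scale
    det$w <- det$w / lb$scale
    det$h <- det$h / lb$scale
    b <- clip_boxes(det[, c("cx", "cy", "w", "h")], ncol(image), nrow(image))
    det <- det[attr(b, "kept"), , drop = FALSE]
    det[, c("cx", "cy", "w", "h")] <- b
  }
  det$class_id <- if (nrow(det)) as.integer(det$class) else integer(0)
  det$class <- class_names[det$class_id + 1L]
  rownames(det) <- NULL
  det[, c("class_id", "class", "score", "cx", "cy", "w", "h")]
}

# Flatten all head tensors of one batch element into a data frame of raw
# predictions (decoded pixel boxes + objectness / best-class logits).
decode_heads <- function(heads, cfg, batch_index = 1L) {
  na <- nrow(cfg$anchors[[1]])
  per <- 5L + cfg$num_classes
  out <- vector("list", length(heads))
  for (s in seq_along(heads)) {
    hmat <- heads[[s]][, , , batch_index, drop = FALSE]
    d <- dim(hmat)  # (na*per, gh, gw, 1)
    gh <- d[2]; gw <- d[3]
    stride <- cfg$strides[s]
    cells <- expand.grid(gy = seq_len(gh) - 1L, gx = seq_len(gw) - 1L)
    rows <- vector("list", na)
    for (a in seq_len(na)) {
      off <- (a - 1L) * per
      chs <- hmat[off + 1:per, , , 1L, drop = FALSE]
      dim(chs) <- c(per, gh * gw)
      toff <- t(chs[1:4, , drop = FALSE])
      boxes <- decode_boxes(toff, cells$gx, cells$gy,
                            cfg$anchors[[s]][a, "w"], cfg$anchors[[s]][a, "h"],
                            stride)
      cls <- chs[6:per, , drop = FALSE]
      best <- max.col(t(cls))
      rows[[a]] <- data.frame(
        scale = s, anchor = a, gx = cells$gx, gy = cells$gy,
        cx = boxes[, "cx"], cy = boxes[, "cy"],
        w = boxes[, "w"], h = boxes[, "h"],
        obj = chs[5L, ], cls_best = cls[cbind(best, seq_len(gh * gw))],
        class_id = best - 1L)
    }
    out[[s]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}
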