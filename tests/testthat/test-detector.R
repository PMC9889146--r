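tiny_cfg <- function(size = 64L, nc = 10L)
  model_config(input_size = size, width_multiple = 0.0625, num_classes = nc)

test_that("a centered box is assigned to the right cell on a fitting scale", {
  cfg <- tiny_cfg()
  # 16x16 box at (36, 28): matches the stride-8 anchors (20, 20)-ish
  gt <- data.frame(class = 2L, cx = 36, cy = 28, w = 16, h = 16)
  a <- assign_targets(gt, cfg)
  expect_gt(nrow(a), 0)
  s1 <- a[a$scale == 1, ]
  expect_true(nrow(s1) > 0)
  # center cell (gi, gj) = floor(36/8), floor(28/8) = (4, 3) must be present
  expect_true(any(s1$gi == 4 & s1$gj == 3))
  # plus exactly two neighbor cells per (scale, anchor)
  one <- s1[s1$anchor == s1$anchor[1], ]
  expect_equal(nrow(one), 3L)
  expect_true(all(a$class == 2L))
})

test_that("empty and out-of-image ground truth follow the contract", {
  cfg <- tiny_cfg()
  empty <- assign_targets(data.frame(class = integer(), cx = numeric(),
                                     cy = numeric(), w = numeric(),
                                     h = numeric()), cfg)
  expect_equal(nrow(empty), 0L)
  expect_warning(
    a <- assign_targets(data.frame(class = 0L, cx = 2, cy = 30, w = 12,
                                   h = 12), cfg),
    "clipping")
  expect_true(all(a$cx - a$w / 2 >= 0))
})

test_that("assignment is invariant to ground-truth ordering", {
  cfg <- tiny_cfg()
  set.seed(73)
  gt <- data.frame(class = sample(0:9, 6, TRUE),
                   cx = runif(6, 10, 54), cy = runif(6, 10, 54),
                   w = runif(6, 8, 20), h = runif(6, 8, 20))
  a1 <- assign_targets(gt, cfg)
  for (perm in 1:5) {
    p <- sample.int(6)
    a2 <- assign_targets(gt[p, ], cfg)
    a2$gt <- p[a2$gt]  # map row indices back to the original order
    key <- function(d) do.call(paste, d[order(d$scale, d$anchor, d$gi,
                                              d$gj),
                                        c("scale", "anchor", "gi", "gj",
                                          "gt", "class")])
    expect_identical(key(a2), key(a1))
  }
})

test_that("NMS worked examples and the greedy O(n^2) oracle", {
  d <- data.frame(class = "A", score = c(0.9, 0.8),
                  cx = c(10, 11), cy = c(10, 10.5), w = 8, h = 8)
  expect_equal(nrow(nms(d, 0.45, 0.25)), 1L)
  expect_equal(nms(d, 0.45, 0.25)$score, 0.9)
  d2 <- data.frame(class = "A", score = c(0.9, 0.8),
                   cx = c(10, 40), cy = 10, w = 8, h = 8)
  expect_equal(nrow(nms(d2, 0.45, 0.25)), 2L)
  expect_error(nms(d2, 1.2, 0.2), "\\[0, 1\\]")
  set.seed(77)
  for (rep_i in 1:5) {
    d3 <- data.frame(class = sample(c("A", "B"), 20, TRUE),
                     score = runif(20),
                     cx = runif(20, 10, 50), cy = runif(20, 10, 50),
                     w = runif(20, 6, 18), h = runif(20, 6, 18))
    got <- nms(d3, 0.45, 0.2)
    ref <- nms_oracle(d3, 0.45, 0.2)
    expect_equal(got$score, ref$score)
    expect_equal(got$cx, ref$cx)
  }
})

test_that("box codec round-trips through a grid cell to under 1 px", {
  set.seed(79)
  for (i in 1:50) {
    stride <- sample(c(8, 16, 32), 1)
    gx <- sample(0:6, 1); gy <- sample(0:6, 1)
    aw <- runif(1, 8, 40); ah <- runif(1, 8, 40)
    b <- bbox(cx = (gx + runif(1)) * stride, cy = (gy + runif(1)) * stride,
              w = aw * runif(1, 0.3, 3.5), h = ah * runif(1, 0.3, 3.5))
    t <- encode_boxes(b, gx, gy, aw, ah, stride)
    back <- decode_boxes(t, gx, gy, aw, ah, stride)
    expect_lt(max(abs(back - b)), 1)
  }
  # unrepresentable: center too far from the cell
  expect_error(encode_boxes(bbox(100, 100, 10, 10), 0, 0, 10, 10, 8),
               "not representable")
})

test_that("same-seed training runs produce identical loss histories", {
  fx <- fixture_single_image_set(size = 64, n = 4)
  cfg <- tiny_cfg()
  runs <- lapply(1:2, function(i) {
    m <- build_model(cfg, seed = 5)
    m <- train_detector(m, fx$dataset, epochs = 2, lr = 0.02,
                        batch_size = 4, seed = 17)
    m$history
  })
  expect_identical(runs[[1]], runs[[2]])
  # and a different seed shuffles differently once there is > 1 batch
  expect_error(train_detector(build_model(cfg, seed = 5),
                              list(images = list(), boxes = list()),
                              epochs = 1),
               "empty dataset")
})

test_that("training reduces the loss on an easy single-image task", {
  fx <- fixture_single_image_set(size = 128, n = 8)
  cfg <- model_config(input_size = 128, width_multiple = 0.125,
                      num_classes = 10)
  m <- build_model(cfg, seed = 1)
  m <- train_detector(m, fx$dataset, epochs = 20, lr = 0.05, batch_size = 8,
                      weights = loss_weights(0.5, 1, 0.5), seed = 11)
  h <- m$history
  expect_lt(h$total[20], h$total[1])
  expect_lt(h$l_cls[20], h$l_cls[1])
})

test_that("with zero box weight the box outputs stay untrained", {
  fx <- fixture_single_image_set(size = 64, n = 4)
  cfg <- tiny_cfg()
  m <- build_model(cfg, seed = 5)
  per <- 5L + cfg$num_classes
  box_cols <- as.vector(outer(1:4, (0:2) * per, `+`))
  before <- lapply(m$head_names, function(h) m$net$nodes[[h]]$W[, box_cols])
  m <- train_detector(m, fx$dataset, epochs = 2, lr = 0.02, batch_size = 4,
                      weights = loss_weights(a = 0.5, b = 1, c = 0),
                      weight_decay = 0, seed = 19)
  after <- lapply(m$head_names, function(h) m$net$nodes[[h]]$W[, box_cols])
  expect_identical(before, after)
  # while the objectness columns did move
  obj_cols <- (0:2) * per + 5L
  expect_false(identical(
    lapply(m$head_names, function(h) m$net$nodes[[h]]$W[, obj_cols]),
    before))
})

test_that("an untrained model yields nothing above the score threshold on
           a blank image", {
  cfg <- tiny_cfg()
  m <- build_model(cfg, seed = 2)
  det <- predict_image(m, matrix(0.5, 64, 64), score_threshold = 0.25)
  expect_equal(nrow(det), 0L)
  expect_error(predict_image(m, array(0, c(4, 4, 3))), "matrix")
})

test_that("a model overfit on one image recovers its boxes with IoU > 0.8", {
  fx <- fixture_single_image_set(section = "3VT", size = 128, seed = 5,
                                 n = 8)
  cfg <- model_config(input_size = 128, width_multiple = 0.125,
                      num_classes = 10)
  m <- build_model(cfg, seed = 1)
  m <- train_detector(m, fx$dataset, epochs = 60, lr = 0.05, batch_size = 8,
                      weights = loss_weights(0.5, 1, 0.5), seed = 11)
  # low operating threshold, as in AP evaluation: the example is about
  # box recovery, and objectness scores rise slowly under 1/N averaging
  det <- predict_image(m, fx$annotated$image, score_threshold = 0.05)
  gt <- fx$annotated$boxes
  recovered <- vapply(seq_len(nrow(gt)), function(i) {
    dd <- det[det$class == gt$class[i], , drop = FALSE]
    if (!nrow(dd)) return(0)
    max(box_iou_matrix(as_bbox(gt[i, c("cx", "cy", "w", "h")]),
                       as_bbox(dd[, c("cx", "cy", "w", "h")])))
  }, numeric(1))
  expect_true(all(recovered > 0.8),
              info = paste("per-structure IoU:",
                           paste(round(recovered, 3), collapse = ", ")))
})
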