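unit_box_at <- function(cx, cy) bbox(cx, cy, 1, 1)

test_that("angle cost hits its exact landmark values", {
  # horizontally aligned centers: alpha = 0
  expect_identical(angle_cost(unit_box_at(0, 5), unit_box_at(9, 5)), 0)
  # vertically aligned centers: alpha = pi/2
  expect_identical(angle_cost(unit_box_at(4, 0), unit_box_at(4, 7)), 0)
  # 45 degrees
  expect_identical(angle_cost(unit_box_at(0, 0), unit_box_at(3, 3)), 1)
  # 3-4-5 triangle: sin(2a) = 2 * 0.8 * 0.6
  expect_equal(angle_cost(unit_box_at(0, 0), unit_box_at(3, 4)), 0.96)
  # coincident centers: epsilon rule
  expect_identical(angle_cost(unit_box_at(2, 2), unit_box_at(2, 2)), 0)
})

test_that("angle cost equals 1 - 2 sin^2(arcsin(ch/sigma) - pi/4) to 1e-12", {
  set.seed(3)
  n <- 1000
  p <- bbox(runif(n, 0, 50), runif(n, 0, 50), runif(n, 1, 9), runif(n, 1, 9))
  g <- bbox(runif(n, 0, 50), runif(n, 0, 50), runif(n, 1, 9), runif(n, 1, 9))
  lam <- angle_cost(p, g)
  sigma <- sqrt((g[, "cx"] - p[, "cx"])^2 + (g[, "cy"] - p[, "cy"])^2)
  ch <- abs(g[, "cy"] - p[, "cy"])
  printed <- 1 - 2 * sin(asin(pmin(ch / sigma, 1)) - pi / 4)^2
  expect_lt(max(abs(lam - printed)), 1e-12)
  expect_true(all(lam >= 0 & lam <= 1))
})

test_that("distance cost matches direct evaluation and its conventions", {
  # coincident centers
  expect_equal(distance_cost(bbox(3, 3, 2, 2), bbox(3, 3, 4, 4)), 0)
  # gamma = 2, horizontal offset of half the enclosing width, same row:
  # px = (dx / cw)^2 = 1/4, py = 0 -> 1 - exp(-0.5)
  p <- bbox(1, 1, 2, 2); g <- bbox(3, 1, 2, 2)  # cw = 4, dx = 2
  expect_equal(distance_cost(p, g, angle = 0), 1 - exp(-0.5))
  expect_equal(distance_cost(p, g), 1 - exp(-0.5))  # aligned: angle = 0
})

test_that("distance cost grows monotonically with center offset", {
  offs <- seq(0.2, 6, by = 0.2)
  # fixed enclosing rectangle via a large gt box
  g <- bbox(10, 10, 16, 16)
  vals <- vapply(offs, function(dx)
    distance_cost(bbox(10 + dx, 10, 2, 2), g), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("shape cost matches direct evaluation and decreases in theta", {
  expect_equal(shape_cost(bbox(0, 0, 3, 5), bbox(9, 9, 3, 5)), 0)
  expect_equal(shape_cost(bbox(0, 0, 4, 2), bbox(0, 0, 2, 2)),
               (1 - exp(-0.5))^4)
  vals <- vapply(2:6, function(th)
    shape_cost(bbox(0, 0, 4, 3), bbox(0, 0, 2, 2), siou_params(th)),
    numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("theta is validated and clamped to [2, 6]", {
  expect_equal(siou_params(4)$theta, 4)
  expect_warning(p <- siou_params(8), "clamped")
  expect_equal(p$theta, 6)
  expect_warning(p <- siou_params(1), "clamped")
  expect_equal(p$theta, 2)
  expect_error(siou_params(c(2, 3)), "single")
})

test_that("SIoU loss: zero iff identical, bounded, dominates 1 - IoU", {
  a <- bbox(10, 10, 6, 4)
  expect_identical(siou_box_loss(a, a), 0)
  set.seed(9)
  p <- bbox(runif(300, 0, 40), runif(300, 0, 40), runif(300, 1, 15),
            runif(300, 1, 15))
  g <- bbox(runif(300, 0, 40), runif(300, 0, 40), runif(300, 1, 15),
            runif(300, 1, 15))
  l <- siou_box_loss(p, g)
  expect_true(all(l >= 0 & l <= 3))
  expect_true(all(l >= 1 - box_iou(p, g) - 1e-12))
  expect_gt(min(l[1:10]), 0)
})

test_that("disjoint equal-shape boxes give 1 + distance_cost / 2", {
  p <- bbox(2, 2, 2, 2); g <- bbox(12, 2, 2, 2)
  expect_equal(siou_box_loss(p, g),
               1 + distance_cost(p, g, angle = angle_cost(p, g)) / 2)
})

test_that("all four SIoU terms are symmetric in pred and gt", {
  set.seed(11)
  p <- bbox(runif(50, 0, 30), runif(50, 0, 30), runif(50, 1, 9),
            runif(50, 1, 9))
  g <- bbox(runif(50, 0, 30), runif(50, 0, 30), runif(50, 1, 9),
            runif(50, 1, 9))
  expect_equal(angle_cost(p, g), angle_cost(g, p))
  expect_equal(distance_cost(p, g), distance_cost(g, p))
  expect_equal(shape_cost(p, g), shape_cost(g, p))
  expect_equal(box_iou(p, g), box_iou(g, p))
})

test_that("siou_terms reports consistent intermediate quantities", {
  tm <- siou_terms(bbox(0, 0, 4, 4), bbox(3, 4, 2, 2))
  expect_equal(tm$sigma, 5)
  expect_equal(tm$ch, 4)
  expect_lte(tm$ch, tm$sigma)
  expect_equal(tm$gamma, 2 - tm$angle_cost)
  expect_equal(tm$cw_enclose, 6)   # [-2, 4]
  expect_equal(tm$ch_enclose, 7)   # [-2, 5]
  expect_true(tm$distance_cost >= 0 && tm$distance_cost <= 2)
  expect_true(tm$shape_cost >= 0 && tm$shape_cost <= 2)
})

test_that("finite-difference SIoU gradient is a descent direction", {
  set.seed(13)
  p <- bbox(runif(40, 5, 35), runif(40, 5, 35), runif(40, 2, 12),
            runif(40, 2, 12))
  g <- bbox(runif(40, 5, 35), runif(40, 5, 35), runif(40, 2, 12),
            runif(40, 2, 12))
  gr <- siou_box_grad(p, g)
  l0 <- siou_box_loss(p, g)
  step <- 1e-3
  p2 <- p
  p2[, ] <- p[, ] - step * gr / pmax(sqrt(rowSums(gr^2)), 1e-12)
  p2[, "w"] <- pmax(p2[, "w"], 0.1); p2[, "h"] <- pmax(p2[, "h"], 0.1)
  l1 <- siou_box_loss(p2, g)
  moved <- sqrt(rowSums(gr^2)) > 1e-6
  expect_true(all(l1[moved] < l0[moved]))
})
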