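test_that("confusion-count rates match direct quotients", {
  cts <- confusion_counts(tp = 9, fp = 1, tn = 5, fn = 3)
  expect_equal(precision(cts), 0.9)
  expect_equal(recall(cts), 9 / 12)
  expect_equal(specificity(cts), 5 / 6)
  expect_equal(accuracy(cts), 14 / 18)
  set.seed(41)
  for (i in 1:20) {
    v <- rpois(4, 10) + 1
    cts <- confusion_counts(v[1], v[2], v[3], v[4])
    expect_equal(precision(cts), v[1] / (v[1] + v[2]))
    expect_equal(recall(cts), v[1] / (v[1] + v[4]))
    expect_equal(specificity(cts), v[3] / (v[3] + v[2]))
    expect_equal(accuracy(cts), (v[1] + v[3]) / sum(v))
  }
  expect_equal(recall(confusion_counts(tp = 4, fn = 0)), 1)
  expect_equal(accuracy(confusion_counts(5, 5, 5, 5)), 0.5)
})

test_that("zero denominators are reported as NA, not silent zeros", {
  expect_warning(p <- precision(confusion_counts(tp = 0, fp = 0, tn = 2)),
                 "undefined")
  expect_true(is.na(p))
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("F1 is the harmonic mean with its fixed point and bounds", {
  for (x in c(0.1, 0.5, 0.9)) expect_equal(f1(x, x), x)
  set.seed(43)
  p <- runif(50); r <- runif(50)
  f <- mapply(f1, p, r)
  expect_true(all(f >= pmin(p, r) - 1e-12 & f <= pmax(p, r) + 1e-12))
  expect_warning(z <- f1(0, 0), "undefined")
  expect_equal(z, 0)
})

test_that("F1 reproduces the benchmark table entries", {
  expect_equal(round(f1(0.995, 1.00), 4), 0.9975)
  expect_equal(round(f1(0.909, 0.755), 4), 0.8249)
})

test_that("average precision handles the trivial cases", {
  gt <- data.frame(image = "a", cx = 10, cy = 10, w = 4, h = 4)
  hit <- data.frame(image = "a", score = 0.9, cx = 10, cy = 10, w = 4, h = 4)
  expect_equal(average_precision(hit, gt), 1)
  miss <- data.frame(image = "a", score = 0.9, cx = 30, cy = 30, w = 4, h = 4)
  expect_equal(average_precision(miss, gt), 0)
  expect_warning(ap <- average_precision(hit, gt[0, ]), "undefined")
  expect_true(is.na(ap))
  expect_equal(average_precision(hit[0, ], gt), 0)
})

test_that("AP equals brute-force PR-curve integration on a ranked list", {
  # 3 ground-truth boxes in one image, 6 ranked detections
  gt <- data.frame(image = "a",
                   cx = c(10, 30, 50), cy = c(10, 10, 10),
                   w = 6, h = 6)
  det <- data.frame(image = "a",
                    score = c(0.95, 0.9, 0.8, 0.7, 0.6, 0.5),
                    cx = c(10, 70, 30, 90, 50, 10),
                    cy = c(10, 10, 10, 10, 10, 40),
                    w = 6, h = 6)
  # ranked match flags: hit, miss, hit, miss, hit, miss
  expect_equal(average_precision(det, gt),
               ap_from_flags(c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE), 3))
  set.seed(47)
  for (i in 1:10) {
    n_gt <- sample(2:5, 1)
    gt_i <- data.frame(image = "a", cx = seq_len(n_gt) * 20, cy = 10,
                       w = 6, h = 6)
    nd <- sample(3:8, 1)
    det_i <- data.frame(image = "a", score = sort(runif(nd), TRUE),
                        cx = sample(seq_len(8) * 20, nd), cy = 10,
                        w = 6, h = 6)
    flags <- logical(nd)
    used <- logical(n_gt)
    for (k in seq_len(nd)) {
      j <- which(gt_i$cx == det_i$cx[k] & !used)
      if (length(j)) { flags[k] <- TRUE; used[j[1]] <- TRUE }
    }
    expect_equal(average_precision(det_i, gt_i), ap_from_flags(flags, n_gt))
  }
})

test_that("AP is non-increasing in the match IoU threshold", {
  set.seed(49)
  gt <- data.frame(image = "a", cx = c(10, 30), cy = 10, w = 8, h = 8)
  det <- data.frame(image = "a", score = c(0.9, 0.8, 0.7),
                    cx = c(11.5, 31, 28), cy = c(10, 12, 10),
                    w = c(8, 7, 9), h = c(8, 8, 8))
  aps <- vapply(seq(0.1, 0.9, 0.1), function(th)
    average_precision(det, gt, th), numeric(1))
  expect_true(all(diff(aps) <= 1e-12))
})

test_that("mAP is the arithmetic mean over defined classes", {
  expect_equal(mean_average_precision(0.7), 0.7)
  expect_equal(mean_average_precision(c(0.5, 0.9)), 0.7)
  expect_equal(mean_average_precision(c(0.9, 0.5)), 0.7)
  expect_equal(mean_average_precision(rep(0.83, 7)), 0.83)
  expect_warning(m <- mean_average_precision(c(0.6, NA, 0.8)), "excluded")
  expect_equal(m, 0.7)
  expect_error(mean_average_precision(numeric()), "at least one")
})

test_that("McNemar statistic, branches and exact-binomial agreement", {
  # no discordance asymmetry
  t0 <- mcnemar_test(b = 7, c = 7)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  expect_equal(mcnemar_test(b = 0, c = 0)$p_value, 1)
  # corrected chi-square value on the worked example
  t1 <- mcnemar_test(b = 5, c = 15)
  expect_equal(t1$statistic, 81 / 20)
  expect_equal(t1$statistic, 4.05)
  # small-count p-values are exact binomial
  for (bc in list(c(5, 15), c(2, 9), c(0, 6), c(11, 12))) {
    t <- mcnemar_test(b = bc[1], c = bc[2])
    expect_equal(t$method, "exact_binomial")
    expect_equal(t$p_value,
                 stats::binom.test(bc[1], sum(bc), 0.5)$p.value)
  }
  # large counts use the corrected chi-square, matching stats::mcnemar.test
  t2 <- mcnemar_test(b = 10, c = 25)
  ref <- stats::mcnemar.test(matrix(c(40, 10, 25, 40), 2, 2))
  expect_equal(t2$statistic, unname(ref$statistic))
  expect_equal(t2$p_value, unname(ref$p.value))
  expect_true(t2$significant == (t2$p_value < 0.05))
})

test_that("rater report: perfect rater and self-comparison degenerate cases", {
  ref <- c("4CH", "3VV", "3VT", "RVOT", "LVOT", "NONSTANDARD",
           "4CH", "3VT", "NONSTANDARD", "LVOT")
  cmp <- rater_report(list(A = ref, B = ref), reference = ref)
  mA <- cmp$metrics[cmp$metrics$rater == "A", ]
  expect_true(all(mA$sensitivity[!is.na(mA$sensitivity)] == 1))
  expect_true(all(mA$specificity[!is.na(mA$specificity)] == 1))
  expect_true(all(mA$accuracy == 1))
  # identical raters: all McNemar p = 1, nothing significant
  expect_true(all(cmp$mcnemar$p_value == 1))
  expect_false(any(cmp$mcnemar$significant))
})

test_that("rater report recovers programmed flip rates within binomial error", {
  set.seed(53)
  sections <- c("4CH", "3VV", "3VT", "RVOT", "LVOT")
  n <- 600
  ref <- sample(sections, n, replace = TRUE)
  flip_rate <- 0.2
  noisy <- ref
  flip <- runif(n) < flip_rate
  noisy[flip] <- "NONSTANDARD"   # misses: labels a standard case nonstandard
  cmp <- rater_report(list(good = ref, noisy = noisy), reference = ref)
  whole <- cmp$metrics[cmp$metrics$rater == "noisy" &
                       cmp$metrics$section == "Whole", ]
  se <- sqrt(flip_rate * (1 - flip_rate) / n)
  expect_lt(abs(whole$accuracy - (1 - flip_rate)), 4 * se)
  # per-section sensitivity ~ 1 - flip_rate as well
  per <- cmp$metrics[cmp$metrics$rater == "noisy" &
                     cmp$metrics$section != "Whole", ]
  expect_lt(abs(mean(per$sensitivity) - (1 - flip_rate)), 0.06)
  # the noisy rater differs significantly from the good one overall
  mc <- cmp$mcnemar[cmp$mcnemar$section == "Whole", ]
  expect_true(mc$significant)
  expect_error(rater_report(list(A = ref[1:5]), reference = ref),
               "same case set")
})

test_that("detection evaluation is perfect on oracle predictions", {
  set.seed(57)
  gt <- do.call(rbind, lapply(1:5, function(i) {
    n <- sample(2:4, 1)
    data.frame(image = paste0("img", i),
               class = sample(structure_classes(), n),
               cx = runif(n, 20, 100), cy = runif(n, 20, 100),
               w = runif(n, 8, 20), h = runif(n, 8, 20))
  }))
  det <- cbind(gt, score = 0.99)
  rep <- evaluate_detections(det, gt)
  expect_equal(rep$ap[rep$class == "All"], 1)
  expect_true(all(rep$ppv == 1))
  expect_true(all(rep$sensitivity == 1))
  expect_true(all(rep$f1 == 1))
})
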