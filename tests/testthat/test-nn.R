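# naive direct convolution oracle for (C, H, W, N) tensors
conv_oracle <- function(x, Wmat, k, stride, pad, cout) {
  d <- dim(x)
  ho <- (d[2] + 2 * pad - k) %/% stride + 1
  wo <- (d[3] + 2 * pad - k) %/% stride + 1
  out <- array(0, c(cout, ho, wo, d[4]))
  for (n in seq_len(d[4])) for (oc in seq_len(cout))
    for (i in seq_len(ho)) for (j in seq_len(wo)) {
      acc <- 0
      for (dw in seq_len(k)) for (dh in seq_len(k)) for (c in seq_len(d[1])) {
        hi <- (i - 1) * stride - pad + dh
        wi <- (j - 1) * stride - pad + dw
        if (hi >= 1 && hi <= d[2] && wi >= 1 && wi <= d[3]) {
          wrow <- (dw - 1) * k * d[1] + (dh - 1) * d[1] + c
          acc <- acc + x[c, hi, wi, n] * Wmat[wrow, oc]
        }
      }
      out[oc, i, j, n] <- acc
    }
  out
}

test_that("focus slice is a lossless bijection with the expected layout", {
  x <- array(as.numeric(0:15), c(1, 4, 4, 1))
  y <- focus_slice(x)
  expect_equal(dim(y), c(4L, 2L, 2L, 1L))
  # channel groups are the four parity sub-grids (column-major 0..15)
  expect_equal(as.vector(y[1, , , 1]), c(0, 2, 8, 10))   # odd row, odd col
  expect_equal(as.vector(y[2, , , 1]), c(1, 3, 9, 11))   # even row, odd col
  expect_equal(as.vector(y[3, , , 1]), c(4, 6, 12, 14))  # odd row, even col
  expect_equal(as.vector(y[4, , , 1]), c(5, 7, 13, 15))
  expect_equal(sum(y), sum(x))
  expect_identical(focus_unslice(y), x)
  set.seed(61)
  for (i in 1:5) {
    hh <- 2 * sample(2:9, 1); ww <- 2 * sample(2:9, 1); cc <- sample(1:3, 1)
    x <- array(rnorm(cc * hh * ww * 2), c(cc, hh, ww, 2))
    y <- focus_slice(x)
    expect_equal(dim(y), c(4L * cc, hh %/% 2L, ww %/% 2L, 2L))
    expect_equal(sum(y), sum(x))
    expect_identical(focus_unslice(y), x)
  }
  expect_error(focus_slice(array(0, c(1, 5, 4, 1))), "even")
})

test_that("im2col convolution matches a naive direct-convolution oracle", {
  set.seed(63)
  for (cfgv in list(c(k = 3, s = 1), c(k = 3, s = 2), c(k = 1, s = 1))) {
    k <- unname(cfgv["k"]); s <- unname(cfgv["s"])
    x <- array(rnorm(3 * 8 * 6 * 2), c(3, 8, 6, 2))
    net <- nn_network()
    nn_add(net, "in", "input")
    nn_add(net, "cv", "conv", "in", cin = 3L, cout = 4L, k = as.integer(k),
           stride = as.integer(s), bias = FALSE)
    out <- nn_forward(net, x, outputs = "cv", retain = FALSE)$cv
    ref <- conv_oracle(x, net$nodes$cv$W, k, s, (k - 1) %/% 2, 4)
    expect_equal(out, ref, tolerance = 1e-12)
  }
})

test_that("maxpool same-size pooling matches a direct oracle", {
  set.seed(65)
  x <- array(rnorm(2 * 7 * 7 * 1), c(2, 7, 7, 1))
  net <- nn_network()
  nn_add(net, "in", "input")
  nn_add(net, "mp", "maxpool", "in", k = 3L)
  out <- nn_forward(net, x, outputs = "mp", retain = FALSE)$mp
  for (c in 1:2) for (i in 1:7) for (j in 1:7) {
    ref <- max(x[c, max(1, i - 1):min(7, i + 1),
                 max(1, j - 1):min(7, j + 1), 1])
    expect_equal(out[c, i, j, 1], ref)
  }
})

test_that("network gradients agree with finite differences", {
  set.seed(67)
  cfg <- model_config(input_size = 64, width_multiple = 0.0625,
                      num_classes = 2)
  m <- build_model(cfg, seed = 3)
  net <- m$net
  nn_set_mode(net, TRUE)
  x <- array(runif(64 * 64 * 2), c(1, 64, 64, 2))
  Ws <- NULL
  loss_fn <- function() {
    out <- nn_forward(net, x, retain = TRUE)
    if (is.null(Ws))
      Ws <<- lapply(out, function(o) array(rnorm(length(o)), dim(o)))
    sum(mapply(function(o, w) sum(o * w), out, Ws))
  }
  loss_fn()
  nn_backward(net, Ws)
  g <- net$grads
  probes <- list(c("d3_conv", "W", 11), c("p3_conv", "W", 1),
                 c("head1", "W", 10), c("head1", "b", 3),
                 c("p4_bn", "beta", 1), c("lat6_bn", "gamma", 1))
  eps <- 1e-6
  for (pr in probes) {
    node <- pr[1]; param <- pr[2]; idx <- as.integer(pr[3])
    v0 <- net$nodes[[node]][[param]][idx]
    net$nodes[[node]][[param]][idx] <- v0 + eps
    Lp <- loss_fn()
    net$nodes[[node]][[param]][idx] <- v0 - eps
    Lm <- loss_fn()
    net$nodes[[node]][[param]][idx] <- v0
    fd <- (Lp - Lm) / (2 * eps)
    an <- switch(param, W = g[[node]]$dW[idx], b = g[[node]]$db[idx],
                 gamma = g[[node]]$dgamma[idx],
                 beta = g[[node]]$dbeta[idx])
    rel <- abs(an - fd) / max(abs(fd), abs(an), 1e-2)
    expect_lt(rel, 5e-3, label = paste("grad", node, param, "rel error"))
  }
})

test_that("model builder: shapes, head grids, and width scaling", {
  cfg <- model_config(input_size = 64, width_multiple = 0.125,
                      num_classes = 10)
  m <- build_model(cfg, seed = 0)
  x <- array(runif(64 * 64), c(1, 64, 64, 1))
  nn_set_mode(m$net, FALSE)
  heads <- nn_forward(m$net, x, retain = FALSE)
  for (s in 1:4) {
    g <- 64 %/% cfg$strides[s]
    expect_equal(dim(heads[[s]]), c(3L * 15L, g, g, 1L))
  }
  # doubling width increases the parameter count
  p1 <- nn_count_params(m$net)
  m2 <- build_model(model_config(input_size = 64, width_multiple = 0.25,
                                 num_classes = 10), seed = 0)
  expect_gt(nn_count_params(m2$net), p1)
  expect_error(model_config(input_size = 100), "divisible")
  expect_error(model_config(input_size = 128, spp_kernels = c(2, 4)), "odd")
})

test_that("conv+BN fusion preserves inference outputs to 1e-5", {
  set.seed(71)
  cfg <- model_config(input_size = 64, width_multiple = 0.0625,
                      num_classes = 3)
  m <- build_model(cfg, seed = 5)
  # give BN layers non-trivial running stats via a few training passes
  nn_set_mode(m$net, TRUE)
  for (i in 1:3)
    nn_forward(m$net, array(runif(64 * 64 * 4), c(1, 64, 64, 4)),
               retain = FALSE)
  expect_error(fuse_conv_bn(m$net), "inference mode")
  nn_set_mode(m$net, FALSE)
  x <- array(runif(64 * 64 * 2), c(1, 64, 64, 2))
  before <- nn_forward(m$net, x, retain = FALSE)
  t_unfused <- system.time(nn_forward(m$net, x, retain = FALSE))["elapsed"]
  fuse_conv_bn(m$net)
  after <- nn_forward(m$net, x, retain = FALSE)
  for (s in seq_along(before))
    expect_lt(max(abs(before[[s]] - after[[s]])), 1e-5)
  # no separate normalization work remains
  expect_true(all(vapply(m$net$nodes, function(n) n$op != "bn", logical(1))))
})

test_that("an identity conv + identity BN fuses to an unchanged map", {
  net <- nn_network()
  nn_add(net, "in", "input")
  nn_add(net, "cv", "conv", "in", cin = 1L, cout = 1L, k = 1L, bias = FALSE)
  nn_add(net, "bn", "bn", "cv", c = 1L)
  net$nodes$cv$W <- matrix(1, 1, 1)
  x <- array(rnorm(16), c(1, 4, 4, 1))
  nn_set_mode(net, FALSE)
  y0 <- nn_forward(net, x, outputs = "bn", retain = FALSE)$bn
  expect_equal(y0, x, tolerance = 1e-5)  # rm=0, rv=1, gamma=1, beta=0
  fuse_conv_bn(net)
  y1 <- nn_forward(net, x, outputs = "bn", retain = FALSE)$bn
  expect_equal(y1, y0, tolerance = 1e-12)
})

test_that("network state serializes and reloads to identical outputs", {
  cfg <- model_config(input_size = 64, width_multiple = 0.0625,
                      num_classes = 2)
  m1 <- build_model(cfg, seed = 8)
  st <- nn_state(m1$net)
  m2 <- build_model(cfg, seed = 99)  # different init
  nn_load_state(m2$net, st)
  x <- array(runif(64 * 64), c(1, 64, 64, 1))
  nn_set_mode(m1$net, FALSE); nn_set_mode(m2$net, FALSE)
  o1 <- nn_forward(m1$net, x, retain = FALSE)
  o2 <- nn_forward(m2$net, x, retain = FALSE)
  expect_identical(o1, o2)
})
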