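#' @useDynLib echoplane, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

silu <- function(x) x * sigmoid(x)

# ---------------------------------------------------------------------------
# A minimal static-graph CNN engine.  Tensors are R arrays with dim
# (C, H, W, N); nodes are stored in insertion (topological) order inside an
# environment so parameter updates mutate in place.  Each op implements a
# forward and a backward rule; convolution gathers patches with the Rcpp
# im2col kernel and multiplies with BLAS.
# ---------------------------------------------------------------------------

#' Create an empty network graph
#'
#' The detector is assembled as a static directed acyclic graph of
#' primitive ops (`input`, `conv`, `bn`, `silu`, `focus`, `maxpool`,
#' `upsample`, `concat`, `add`).  [build_model()] is the user-facing
#' constructor; these primitives are exported for inspection and testing.
#'
#' @return an environment holding `nodes` (named list, topological order)
#'   and bookkeeping fields.
#' @keywords internal
#' @export
nn_network <- function() {
  net <- new.env(parent = emptyenv())
  net$nodes <- list()
  net$mode <- "train"
  net$fused <- FALSE
  net
}

#' @rdname nn_network
#' @param net a network environment.
#' @param name unique node name.
#' @param op one of the primitive op names.
#' @param from character vector of upstream node names.
#' @param ... op parameters (`cin`, `cout`, `k`, `stride`, `bias` for
#'   `conv`; `c` for `bn`; `k` for `maxpool`).
#' @export
nn_add <- function(net, name, op, from = character(), ...) {
  if (name %in% names(net$nodes)) stop("duplicate node name: ", name)
  missing_from <- setdiff(from, names(net$nodes))
  if (length(missing_from))
    stop("unknown upstream node(s): ", paste(missing_from, collapse = ", "))
  node <- list(name = name, op = op, from = from, ...)
  if (op == "conv") {
    k <- node$k %||% 3L
    fan_in <- node$cin * k * k
    node$k <- k
    node$stride <- node$stride %||% 1L
    node$pad <- (k - 1L) %/% 2L
    node$W <- matrix(stats::rnorm(fan_in * node$cout, sd = sqrt(2 / fan_in)),
                     fan_in, node$cout)
    node$b <- if (isTRUE(node$bias)) numeric(node$cout) else NULL
  } else if (op == "bn") {
    node$gamma <- rep(1, node$c)
    node$beta <- numeric(node$c)
    node$rm <- numeric(node$c)
    node$rv <- rep(1, node$c)
    node$eps <- 1e-5
    node$momentum <- 0.1
  } else if (op == "maxpool") {
    stopifnot(node$k %% 2 == 1)
  }
  net$nodes[[name]] <- node
  invisible(net)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Switch a network between training and inference mode
#'
#' Training mode uses batch statistics in the batch-norm layers and
#' updates their running estimates; inference mode uses the running
#' estimates.
#'
#' @param net a network environment.
#' @param training logical.
#' @export
nn_set_mode <- function(net, training) {
  net$mode <- if (training) "train" else "eval"
  invisible(net)
}

#' Space-to-depth focus slice
#'
#' Stacks the four 2x2-parity sub-grids of the image into channels: a
#' `(C, H, W)` tensor becomes `(4C, H/2, W/2)`.  Lossless: every input
#' value appears exactly once in the output, and [focus_unslice()] is the
#' exact inverse.
#'
#' @param x array with dim `(C, H, W, N)`; `H` and `W` must be even.
#' @return array with dim `(4C, H/2, W/2, N)`.
#' @export
focus_slice <- function(x) {
  d <- dim(x)
  if (length(d) != 4L) stop("focus_slice expects a (C, H, W, N) array")
  if (d[2] %% 2 != 0 || d[3] %% 2 != 0)
    stop("focus_slice needs even height and width")
  oh <- seq(1L, d[2], 2L); ow <- seq(1L, d[3], 2L)
  out <- array(0, c(4L * d[1], d[2] %/% 2L, d[3] %/% 2L, d[4]))
  ci <- seq_len(d[1])
  out[ci, , , ]            <- x[, oh,     ow,     , drop = FALSE]
  out[ci + d[1], , , ]     <- x[, oh + 1L, ow,    , drop = FALSE]
  out[ci + 2L * d[1], , , ] <- x[, oh,     ow + 1L, , drop = FALSE]
  out[ci + 3L * d[1], , , ] <- x[, oh + 1L, ow + 1L, , drop = FALSE]
  out
}

#' @rdname focus_slice
#' @export
focus_unslice <- function(x) {
  d <- dim(x)
  c0 <- d[1] %/% 4L
  out <- array(0, c(c0, d[2] * 2L, d[3] * 2L, d[4]))
  oh <- seq(1L, d[2] * 2L, 2L); ow <- seq(1L, d[3] * 2L, 2L)
  ci <- seq_len(c0)
  out[, oh,      ow,      ] <- x[ci, , , , drop = FALSE]
  out[, oh + 1L, ow,      ] <- x[ci + c0, , , , drop = FALSE]
  out[, oh,      ow + 1L, ] <- x[ci + 2L * c0, , , , drop = FALSE]
  out[, oh + 1L, ow + 1L, ] <- x[ci + 3L * c0, , , , drop = FALSE]
  out
}

upsample2 <- function(x) {
  d <- dim(x)
  x[, rep(seq_len(d[2]), each = 2L), rep(seq_len(d[3]), each = 2L), ,
    drop = FALSE]
}

upsample2_bwd <- function(g) {
  d <- dim(g)
  h2 <- d[2] %/% 2L; w2 <- d[3] %/% 2L
  dim(g) <- c(d[1], 2L, h2, 2L, w2, d[4])
  out <- colSums(aperm(g, c(2, 4, 1, 3, 5, 6)), dims = 2L)
  dim(out) <- c(d[1], h2, w2, d[4])
  out
}

conv_fwd <- function(node, x) {
  d <- dim(x)
  cols <- im2col_cpp(x, d[1], d[2], d[3], d[4],
                     node$k, node$k, node$stride, node$pad)
  out <- crossprod(node$W, cols)
  if (!is.null(node$b)) out <- out + node$b
  ho <- (d[2] + 2 * node$pad - node$k) %/% node$stride + 1L
  wo <- (d[3] + 2 * node$pad - node$k) %/% node$stride + 1L
  dim(out) <- c(node$cout, ho, wo, d[4])
  list(out = out, cache = list(cols = cols, xdim = d))
}

conv_bwd <- function(node, cache, g) {
  d <- dim(g)
  gm <- g; dim(gm) <- c(d[1], prod(d[-1]))
  dW <- cache$cols %*% t(gm)
  db <- if (!is.null(node$b)) rowSums(gm) else NULL
  dcols <- node$W %*% gm
  dx <- col2im_cpp(dcols, cache$xdim[1], cache$xdim[2], cache$xdim[3],
                   cache$xdim[4], node$k, node$k, node$stride, node$pad)
  list(dx = dx, dW = dW, db = db)
}

bn_fwd <- function(node, x, training) {
  if (training) {
    r <- bn_fwd_train_cpp(x, length(node$gamma), node$gamma, node$beta,
                          node$eps)
    upd <- list(rm = (1 - node$momentum) * node$rm + node$momentum * r$mu,
                rv = (1 - node$momentum) * node$rv + node$momentum * r$var)
    list(out = r$y, cache = list(xhat = r$xhat, ivar = r$ivar, d = dim(x)),
         update = upd)
  } else {
    y <- bn_fwd_eval_cpp(x, length(node$gamma), node$gamma, node$beta,
                         node$rm, node$rv, node$eps)
    list(out = y, cache = NULL, update = NULL)
  }
}

bn_bwd <- function(node, cache, g) {
  r <- bn_bwd_cpp(g, cache$xhat, cache$ivar, node$gamma,
                  length(node$gamma))
  list(dx = r$dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

#' Run a forward pass through the graph
#'
#' @param net a network environment.
#' @param x input array with dim `(C, H, W, N)`.
#' @param outputs names of nodes whose outputs to return (default: the
#'   nodes marked as heads at build time, else the last node).
#' @param retain keep intermediate caches for a subsequent
#'   [nn_backward()] call (implied by training mode).
#' @return a named list of output arrays.
#' @export
nn_forward <- function(net, x, outputs = NULL, retain = NULL) {
  training <- net$mode == "train"
  if (is.null(retain)) retain <- training
  if (is.null(outputs)) outputs <- net$heads %||% utils::tail(names(net$nodes), 1)
  vals <- list()
  net$cache <- list()
  for (name in names(net$nodes)) {
    node <- net$nodes[[name]]
    val <- switch(node$op,
      input = x,
      conv = {
        r <- conv_fwd(node, vals[[node$from]])
        if (retain) net$cache[[name]] <- r$cache
        r$out
      },
      bn = {
        r <- bn_fwd(node, vals[[node$from]], training)
        if (training && !is.null(r$update)) {
          net$nodes[[name]]$rm <- r$update$rm
          net$nodes[[name]]$rv <- r$update$rv
        }
        if (retain) net$cache[[name]] <- r$cache
        r$out
      },
      silu = {
        xin <- vals[[node$from]]
        if (retain) net$cache[[name]] <- list(x = xin)
        silu_fwd_cpp(xin)
      },
      focus = focus_slice(vals[[node$from]]),
      maxpool = {
        xin <- vals[[node$from]]
        d <- dim(xin)
        r <- maxpool_same_cpp(xin, d[1], d[2], d[3], d[4], node$k)
        if (retain) net$cache[[name]] <- list(argmax = r$argmax, d = d)
        r$out
      },
      upsample = upsample2(vals[[node$from]]),
      concat = {
        ins <- vals[node$from]
        if (retain)
          net$cache[[name]] <- list(chans = vapply(ins, function(v) dim(v)[1],
                                                   integer(1)))
        do.call(abind_c, ins)
      },
      add = vals[[node$from[1]]] + vals[[node$from[2]]],
      identity = vals[[node$from]],
      stop("unknown op: ", node$op)
    )
    vals[[name]] <- val
  }
  net$shapes <- lapply(vals, dim)
  vals[outputs]
}

# channel-axis concatenation for (C, H, W, N) arrays
abind_c <- function(...) {
  ins <- list(...)
  ds <- lapply(ins, dim)
  cs <- vapply(ds, `[`, integer(1), 1L)
  out <- array(0, c(sum(cs), ds[[1]][-1]))
  at <- 0L
  for (i in seq_along(ins)) {
    out[at + seq_len(cs[i]), , , ] <- ins[[i]]
    at <- at + cs[i]
  }
  out
}

#' Backpropagate gradients through the graph
#'
#' @param net a network environment whose last [nn_forward()] call
#'   retained caches.
#' @param grad_outputs named list of gradient arrays, keyed by node name.
#' @return invisibly, the network; parameter gradients are stored in
#'   `net$grads[[node]]`.
#' @export
nn_backward <- function(net, grad_outputs) {
  grads <- grad_outputs
  net$grads <- list()
  acc <- function(tbl, name, g) {
    if (is.null(tbl[[name]])) tbl[[name]] <- g else tbl[[name]] <- tbl[[name]] + g
    tbl
  }
  for (name in rev(names(net$nodes))) {
    g <- grads[[name]]
    if (is.null(g)) next
    node <- net$nodes[[name]]
    switch(node$op,
      input = NULL,
      conv = {
        r <- conv_bwd(node, net$cache[[name]], g)
        net$grads[[name]] <- list(dW = r$dW, db = r$db)
        grads <- acc(grads, node$from, r$dx)
      },
      bn = {
        r <- bn_bwd(node, net$cache[[name]], g)
        net$grads[[name]] <- list(dgamma = r$dgamma, dbeta = r$dbeta)
        grads <- acc(grads, node$from, r$dx)
      },
      silu = grads <- acc(grads, node$from,
                          silu_bwd_cpp(net$cache[[name]]$x, g)),
      focus = grads <- acc(grads, node$from, focus_unslice(g)),
      maxpool = {
        cc <- net$cache[[name]]
        grads <- acc(grads, node$from,
                     maxpool_same_bwd_cpp(g, cc$argmax,
                                          cc$d[1], cc$d[2], cc$d[3], cc$d[4]))
      },
      upsample = grads <- acc(grads, node$from, upsample2_bwd(g)),
      concat = {
        cs <- net$cache[[name]]$chans
        at <- 0L
        for (i in seq_along(node$from)) {
          grads <- acc(grads, node$from[i],
                       g[at + seq_len(cs[i]), , , , drop = FALSE])
          at <- at + cs[i]
        }
      },
      add = {
        grads <- acc(grads, node$from[1], g)
        grads <- acc(grads, node$from[2], g)
      },
      identity = grads <- acc(grads, node$from, g)
    )
  }
  invisible(net)
}

#' SGD-with-momentum parameter update
#'
#' @param net network with gradients from [nn_backward()].
#' @param lr learning rate.
#' @param momentum momentum coefficient.
#' @param weight_decay L2 penalty applied to convolution weights only.
#' @export
nn_step <- function(net, lr, momentum = 0.9, weight_decay = 0) {
  for (name in names(net$grads)) {
    node <- net$nodes[[name]]
    g <- net$grads[[name]]
    if (node$op == "conv") {
      dW <- g$dW + weight_decay * node$W
      node$vW <- momentum * (node$vW %||% 0) + dW
      node$W <- node$W - lr * node$vW
      if (!is.null(node$b)) {
        node$vb <- momentum * (node$vb %||% 0) + g$db
        node$b <- node$b - lr * node$vb
      }
    } else if (node$op == "bn") {
      node$vgamma <- momentum * (node$vgamma %||% 0) + g$dgamma
      node$vbeta <- momentum * (node$vbeta %||% 0) + g$dbeta
      node$gamma <- node$gamma - lr * node$vgamma
      node$beta <- node$beta - lr * node$vbeta
    }
    net$nodes[[name]] <- node
  }
  invisible(net)
}

#' Number of trainable parameters in a network
#'
#' @param net a network environment.
#' @return integer parameter count.
#' @export
nn_count_params <- function(net) {
  sum(vapply(net$nodes, function(node) {
    length(node$W) + length(node$b) + length(node$gamma) + length(node$beta)
  }, numeric(1)))
}

#' Recalibrate batch-norm running statistics
#'
#' Replaces every batch-norm layer's running mean/variance with the
#' average of the batch statistics observed over the supplied batches
#' (an equally weighted running average, momentum `1/t` at step `t`).
#' Called at the end of training so that inference-mode outputs track
#' training-mode behavior; the exponentially weighted estimates
#' maintained during SGD lag the drifting activation scale, and that lag
#' compounds across the depth of the network.
#'
#' @param net a network environment.
#' @param tensor_list list of input batch arrays `(C, H, W, N)`.
#' @export
nn_calibrate_bn <- function(net, tensor_list) {
  old_mode <- net$mode
  bn_names <- names(net$nodes)[vapply(net$nodes, function(n) n$op == "bn",
                                      logical(1))]
  if (!length(bn_names) || !length(tensor_list)) return(invisible(net))
  old_mom <- lapply(net$nodes[bn_names], `[[`, "momentum")
  nn_set_mode(net, TRUE)
  for (t in seq_along(tensor_list)) {
    for (b in bn_names) net$nodes[[b]]$momentum <- 1 / t
    nn_forward(net, tensor_list[[t]], retain = FALSE)
  }
  for (b in bn_names) net$nodes[[b]]$momentum <- old_mom[[b]]
  net$mode <- old_mode
  invisible(net)
}

#' Fold batch-norm layers into their preceding convolutions
#'
#' For inference only: each `bn` node whose input is a `conv` is replaced
#' by an identity, with the convolution's weights rescaled by
#' `gamma / sqrt(var + eps)` per output channel and a bias
#' `beta - gamma * mean / sqrt(var + eps)` absorbed, so the fused network
#' reproduces the unfused inference outputs up to floating-point error.
#'
#' @param net a network in inference mode (see [nn_set_mode()]); calling
#'   in training mode is an error.
#' @return the network, modified in place, with `net$fused = TRUE`.
#' @export
fuse_conv_bn <- function(net) {
  if (net$mode != "eval")
    stop("fuse_conv_bn requires inference mode; call nn_set_mode(net, FALSE)")
  for (name in names(net$nodes)) {
    node <- net$nodes[[name]]
    if (node$op != "bn") next
    up <- net$nodes[[node$from]]
    if (up$op != "conv") next
    scale <- node$gamma / sqrt(node$rv + node$eps)
    up$W <- up$W * rep(scale, each = nrow(up$W))
    b0 <- up$b %||% numeric(up$cout)
    up$b <- (b0 - node$rm) * scale + node$beta
    net$nodes[[node$from]] <- up
    node$op <- "identity"
    node$gamma <- node$beta <- node$rm <- node$rv <- NULL
    net$nodes[[name]] <- node
  }
  net$fused <- TRUE
  invisible(net)
}

#' Serialize network weights to a plain list
#'
#' @param net a network environment.
#' @return a list of node parameter lists, suitable for `saveRDS`.
#' @export
nn_state <- function(net) {
  lapply(net$nodes, function(node)
    node[intersect(names(node), c("W", "b", "gamma", "beta", "rm", "rv"))])
}

#' @rdname nn_state
#' @param state a list from `nn_state`.
#' @export
nn_load_state <- function(net, state) {
  for (name in names(state)) {
    for (p in names(state[[name]])) net$nodes[[name]][[p]] <- state[[name]][[p]]
  }
  invisible(net)
}
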