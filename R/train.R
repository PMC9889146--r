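#' Compute the composite detection loss and head gradients for one batch
#'
#' Runs the forward pass, assembles the classification / objectness / box
#' losses from the head tensors and the precomputed target assignments,
#' and backpropagates.  Objectness targets are the IoU between the
#' currently decoded prediction box and its matched ground-truth box
#' (treated as constants), zero at negatives; classification targets are
#' one-hot over positives; the box term is the mean SIoU loss over
#' positives, chained through the decoder.
#'
#' @param model a `detector`.
#' @param tensor input batch, dim `(C, size, size, n)`.
#' @param assignments list of per-image assignment data frames from
#'   [assign_targets()].
#' @param weights [loss_weights()].
#' @param siou [siou_params()].
#' @param backprop run the backward pass and leave gradients on the
#'   network (TRUE during training).
#' @return a `loss_breakdown` with attribute `n_pos`.
#' @export
detection_loss <- function(model, tensor, assignments,
                           weights = loss_weights(), siou = siou_params(),
                           backprop = TRUE) {
  cfg <- model$config
  na <- nrow(cfg$anchors[[1]])
  per <- 5L + cfg$num_classes
  nb <- dim(tensor)[4]
  heads <- nn_forward(model$net, tensor, outputs = model$head_names,
                      retain = backprop)

  pos <- do.call(rbind, lapply(seq_len(nb), function(n) {
    a <- assignments[[n]]
    if (nrow(a)) cbind(a, img = n) else NULL
  }))
  n_pos <- if (is.null(pos)) 0L else nrow(pos)
  n_total <- sum(vapply(heads, function(h) {
    d <- dim(h); na * prod(d[2:4])
  }, numeric(1)))

  grads <- list()
  l_obj_sum <- 0
  l_cls_sum <- 0
  l_box_sum <- 0

  for (s in seq_along(heads)) {
    h <- heads[[s]]
    d <- dim(h)
    G <- array(0, d)
    gh <- d[2]; gw <- d[3]
    obj_ch <- (seq_len(na) - 1L) * per + 5L
    ps <- if (n_pos) pos[pos$scale == s, , drop = FALSE] else pos

    # objectness targets: IoU of decoded positive boxes, 0 elsewhere
    tgt <- array(0, c(na, gh, gw, nb))
    pred_box <- NULL
    tvals <- NULL
    if (!is.null(ps) && nrow(ps)) {
      base <- ((ps$img - 1L) * gw + ps$gi) * gh + ps$gj  # 0-based cell index
      chan0 <- (ps$anchor - 1L) * per
      tidx <- vapply(1:4, function(k) base * d[1] + chan0 + k,
                     numeric(nrow(ps)))
      tidx <- as.vector(matrix(tidx, ncol = 4))  # linear indices, not coords
      tvals <- matrix(h[tidx], ncol = 4)
      aw <- cfg$anchors[[s]][ps$anchor, "w"]
      ah <- cfg$anchors[[s]][ps$anchor, "h"]
      pred_box <- decode_boxes(tvals, ps$gi, ps$gj, aw, ah, cfg$strides[s])
      gt_box <- as.matrix(ps[, c("cx", "cy", "w", "h")])
      iou_t <- pmin(pmax(box_iou(pred_box, as_bbox(gt_box)), 0), 1)
      tgt[cbind(ps$anchor, ps$gj + 1L, ps$gi + 1L, ps$img)] <- iou_t

      # box loss: mean SIoU over positives
      sl <- siou_box_loss(pred_box, as_bbox(gt_box), siou)
      l_box_sum <- l_box_sum + sum(sl)
      dbox <- siou_box_grad(pred_box, as_bbox(gt_box), siou)
      fac <- decode_grad_factors(tvals, aw, ah, cfg$strides[s])
      gt_t <- dbox * fac * weights$c   # per-positive, /N_pos applied later
      G[tidx] <- G[tidx] + as.vector(gt_t)

      # classification: one-hot BCE over positives
      cls_idx <- vapply(seq_len(cfg$num_classes), function(k)
        base * d[1] + chan0 + 5L + k, numeric(nrow(ps)))
      cls_idx <- as.vector(matrix(cls_idx, ncol = cfg$num_classes))
      cls_logits <- matrix(h[cls_idx], ncol = cfg$num_classes)
      onehot <- matrix(0, nrow(ps), cfg$num_classes)
      onehot[cbind(seq_len(nrow(ps)), ps$class + 1L)] <- 1
      l_cls_sum <- l_cls_sum + sum(bce_with_logits(cls_logits, onehot))
      G[cls_idx] <- G[cls_idx] +
        as.vector((sigmoid(cls_logits) - onehot) * weights$a)
    }

    obj_logits <- h[obj_ch, , , , drop = FALSE]
    l_obj_sum <- l_obj_sum + sum(bce_with_logits(obj_logits, tgt))
    G[obj_ch, , , ] <- G[obj_ch, , , , drop = FALSE] +
      (sigmoid(obj_logits) - tgt) * (weights$b / n_total)
    grads[[model$head_names[s]]] <- G
  }

  l_obj <- l_obj_sum / n_total
  if (n_pos > 0) {
    l_cls <- l_cls_sum / n_pos
    l_box <- l_box_sum / n_pos
    # the cls/box gradient entries were accumulated raw; normalize by the
    # batch positive count (the obj part already carries its 1/N factor)
    for (s in seq_along(heads)) {
      nm <- model$head_names[s]
      G <- grads[[nm]]
      obj_ch <- (seq_len(na) - 1L) * per + 5L
      mask <- array(1 / n_pos, dim(G))
      mask[obj_ch, , , ] <- 1
      grads[[nm]] <- G * mask
    }
  } else {
    l_cls <- 0
    l_box <- 0
  }

  if (backprop) nn_backward(model$net, grads)
  out <- total_loss(l_cls, l_obj, l_box, weights)
  attr(out, "n_pos") <- n_pos
  out
}

#' Train the detector on an annotated dataset
#'
#' Plain SGD with momentum, a linear warmup followed by cosine learning
#' rate decay, and seeded shuffling.  No image augmentation is applied
#' (cardiac anatomy is chiral, so mirror flips would corrupt labels).
#' Target assignments are precomputed once per image.
#'
#' @param model a `detector` from [build_model()].
#' @param dataset a list with elements `images` (list of numeric matrices
#'   of the model input size, values in `[0, 1]`) and `boxes` (list of
#'   data frames with `class`, `cx`, `cy`, `w`, `h` in input pixels), as
#'   returned by [load_dataset()] or [as_training_set()].
#' @param epochs number of passes over the data.
#' @param weights [loss_weights()].
#' @param siou [siou_params()].
#' @param lr peak learning rate.
#' @param batch_size minibatch size (BN statistics need > 1).
#' @param momentum,weight_decay SGD hyperparameters.
#' @param warmup_epochs epochs of linear learning-rate ramp.
#' @param seed seed controlling shuffling (weights are seeded at
#'   [build_model()] time); fixed seed gives identical loss histories.
#' @param verbose print one line per epoch.
#' @return the model (modified in place), with the per-epoch loss history
#'   as a data frame in `model$history`.
#' @export
train_detector <- function(model, dataset, epochs = 30,
                           weights = loss_weights(), siou = siou_params(),
                           lr = 0.01, batch_size = 8L, momentum = 0.9,
                           weight_decay = 5e-4, warmup_epochs = 3,
                           seed = 0L, verbose = FALSE) {
  n_img <- length(dataset$images)
  if (n_img == 0L) stop("empty dataset")
  cfg <- model$config
  sz <- cfg$input_size
  ok_dim <- vapply(dataset$images, function(m)
    all(dim(m) == c(sz, sz)), logical(1))
  if (!all(ok_dim))
    stop("all training images must already be at the model input size; ",
         "use as_training_set() to letterbox")
  assignments <- lapply(dataset$boxes, assign_targets, config = cfg)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  nn_set_mode(model$net, TRUE)
  steps_per_epoch <- ceiling(n_img / batch_size)
  total_steps <- epochs * steps_per_epoch
  step <- 0L
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n_img)
    ep_loss <- c(l_cls = 0, l_obj = 0, l_box = 0, total = 0)
    nb_done <- 0L
    for (b in seq_len(steps_per_epoch)) {
      idx <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, n_img)]
      tensor <- array(0, c(cfg$in_channels, sz, sz, length(idx)))
      for (k in seq_along(idx)) tensor[1L, , , k] <- dataset$images[[idx[k]]]
      lb <- detection_loss(model, tensor, assignments[idx], weights, siou,
                           backprop = TRUE)
      step <- step + 1L
      warm <- warmup_epochs * steps_per_epoch
      lr_t <- if (step <= warm && warm > 0) {
        lr * (0.1 + 0.9 * step / warm)
      } else {
        prog <- (step - warm) / max(1, total_steps - warm)
        0.05 * lr + 0.95 * lr * 0.5 * (1 + cos(pi * prog))
      }
      nn_step(model$net, lr_t, momentum, weight_decay)
      ep_loss <- ep_loss + c(lb$l_cls, lb$l_obj, lb$l_box, lb$total)
      nb_done <- nb_done + 1L
    }
    ep_loss <- ep_loss / nb_done
    hist[[ep]] <- data.frame(epoch = ep, l_cls = ep_loss[1],
                             l_obj = ep_loss[2], l_box = ep_loss[3],
                             total = ep_loss[4])
    if (verbose)
      message(sprintf("epoch %3d  cls %.4f  obj %.4f  box %.4f  total %.4f",
                      ep, ep_loss[1], ep_loss[2], ep_loss[3], ep_loss[4]))
  }
  # refresh BN running statistics so inference matches training behavior;
  # sample across the dataset (files are often grouped by section on disk)
  calib_idx <- sample.int(n_img, min(n_img, 8L * batch_size))
  calib <- lapply(split(calib_idx,
                        ceiling(seq_along(calib_idx) / batch_size)),
                  function(ix) {
    tensor <- array(0, c(cfg$in_channels, sz, sz, length(ix)))
    for (k in seq_along(ix)) tensor[1L, , , k] <- dataset$images[[ix[k]]]
    tensor
  })
  nn_calibrate_bn(model$net, calib)
  model$history <- do.call(rbind, hist)
  rownames(model$history) <- NULL
  model
}

#' Letterbox an annotated image list to the model input size
#'
#' @param annotated list of annotated images (elements with `image` and
#'   `boxes`), e.g. from [generate_image()] or [load_dataset()].
#' @param config a [model_config()].
#' @return a training-set list with `images` and `boxes` in input pixels.
#' @export
as_training_set <- function(annotated, config) {
  sz <- config$input_size
  images <- vector("list", length(annotated))
  boxes <- vector("list", length(annotated))
  for (i in seq_along(annotated)) {
    a <- annotated[[i]]
    lb <- letterbox(a$image, sz)
    images[[i]] <- matrix(lb$tensor[1L, , , 1L], sz, sz)
    b <- as.data.frame(a$boxes)
    if (!is.numeric(b$class)) {
      # integer 0-based class ids for assignment/loss
      b$class <- if ("class_id" %in% names(b)) b$class_id else
        match(b$class, structure_classes()) - 1L
    }
    if (nrow(b)) {
      b$cx <- b$cx * lb$scale + lb$left
      b$cy <- b$cy * lb$scale + lb$top
      b$w <- b$w * lb$scale
      b$h <- b$h * lb$scale
    }
    boxes[[i]] <- b
  }
  list(images = images, boxes = boxes)
}
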