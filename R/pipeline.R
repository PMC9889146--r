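#' Pipeline entry points
#'
#' High-level wrappers tying the generator, detector, section rules and
#' evaluation battery into a reproducible file-based pipeline.  Each
#' function logs its resolved configuration and seed, works from a
#' [default_pipeline_config()]-style config, and writes plain-text
#' artifacts (CSV/YAML/PNG; model checkpoints as RDS).  A thin command
#' line dispatcher over these functions ships at
#' `system.file("cli", "echoplane.R", package = "echoplane")`.
#'
#' @param config a `pipeline_config` (list or YAML path).
#' @param out_dir dataset output directory.
#' @param force overwrite a non-empty output directory.
#' @param quiet suppress progress messages.
#' @return `ep_generate`: the manifest data frame, invisibly.
#' @name pipeline
NULL

resolve_config <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  else config <- validate_pipeline_config(config)
  config
}

log_line <- function(quiet, ...) if (!quiet) message(sprintf(...))

#' @rdname pipeline
#' @export
ep_generate <- function(config = default_pipeline_config(), out_dir,
                        force = FALSE, quiet = FALSE) {
  config <- resolve_config(config)
  d <- config$dataset
  log_line(quiet, "generate: %d images/section at %dpx, noise %.3f, seed %d",
           d$n_per_section, d$size, d$noise, config$seeds$data)
  manifest <- generate_dataset(
    out_dir, n_per_section = d$n_per_section,
    split = unlist(d$split), seed = config$seeds$data, size = d$size,
    noise = d$noise, drop_probability = d$drop_probability, force = force)
  counts <- table(manifest$section, manifest$split)
  if (!quiet) {
    message("generated ", nrow(manifest), " images:")
    print(counts)
  }
  invisible(manifest)
}

#' @rdname pipeline
#' @param data_dir dataset root from [ep_generate()].
#' @param checkpoint_path where to save the trained model (RDS).
#' @return `ep_train`: the trained `detector`, invisibly.
#' @export
ep_train <- function(config = default_pipeline_config(), data_dir,
                     checkpoint_path, quiet = FALSE) {
  config <- resolve_config(config)
  ds <- load_dataset(data_dir, split = "train")
  if (!length(ds)) stop("no training images under ", data_dir)
  cfg0 <- as_model_config(config)
  tr <- as_training_set(ds, cfg0)
  all_boxes <- do.call(rbind, tr$boxes)
  anchors <- kmeans_anchors(all_boxes, cfg0, seed = config$seeds$model)
  mcfg <- as_model_config(config, anchors = anchors)
  model <- build_model(mcfg, seed = config$seeds$model)
  log_line(quiet,
           "train: %d images, %d epochs, lr %.4g, batch %d, seed %d",
           length(tr$images), config$train$epochs, config$train$lr,
           config$train$batch_size, config$seeds$train)
  model <- train_detector(
    model, tr, epochs = config$train$epochs,
    weights = do.call(loss_weights, config$loss_weights),
    siou = siou_params(config$siou$theta),
    lr = config$train$lr, batch_size = config$train$batch_size,
    momentum = config$train$momentum,
    weight_decay = config$train$weight_decay,
    warmup_epochs = config$train$warmup_epochs,
    seed = config$seeds$train, verbose = !quiet)
  save_checkpoint(model, checkpoint_path, classes = config$classes)
  hist_path <- sub("\\.rds$", "_history.csv", checkpoint_path)
  utils::write.csv(model$history, hist_path, row.names = FALSE)
  log_line(quiet, "checkpoint: %s; loss history: %s", checkpoint_path,
           hist_path)
  invisible(model)
}

#' Save / load a detector checkpoint
#'
#' A checkpoint holds the serialized weights, the model configuration and
#' the class list; loading rebuilds the graph and verifies that the class
#' count matches.
#'
#' @param model a `detector`.
#' @param path RDS file path.
#' @param classes class-name vector stored alongside the weights.
#' @export
save_checkpoint <- function(model, path, classes = structure_classes()) {
  saveRDS(list(state = nn_state(model$net), config = model$config,
               classes = classes, history = model$history), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expected_classes optional class list the caller requires; a
#'   mismatch with the stored classes is an error.
#' @export
load_checkpoint <- function(path, expected_classes = NULL) {
  ck <- readRDS(path)
  if (!is.null(expected_classes) &&
      !identical(unname(unlist(expected_classes)), unname(ck$classes)))
    stop("checkpoint class list does not match the configuration (",
         length(ck$classes), " stored classes)")
  model <- build_model(ck$config, seed = 0L)
  nn_load_state(model$net, ck$state)
  model$classes <- ck$classes
  model$history <- ck$history
  model
}

collect_predictions <- function(model, ds, config, fuse = TRUE) {
  if (fuse) {
    nn_set_mode(model$net, FALSE)
    if (!model$net$fused) fuse_conv_bn(model$net)
  }
  ev <- config$evaluation
  dets <- lapply(seq_along(ds), function(i) {
    d <- predict_image(model, ds[[i]]$image,
                       score_threshold = min(ev$score_threshold, 0.05),
                       iou_threshold = ev$nms_iou,
                       class_names = config$classes)
    if (nrow(d)) cbind(image = ds[[i]]$filename %||% as.character(i), d)
    else NULL
  })
  do.call(rbind, dets)
}

#' @rdname pipeline
#' @param split dataset split to score.
#' @param out_csv report destination.
#' @return `ep_evaluate`: the per-class evaluation report.
#' @export
ep_evaluate <- function(config = default_pipeline_config(), data_dir,
                        checkpoint_path, out_csv = NULL, split = "test",
                        quiet = FALSE) {
  config <- resolve_config(config)
  model <- load_checkpoint(checkpoint_path,
                           expected_classes = config$classes)
  ds <- load_dataset(data_dir, split = split)
  if (!length(ds)) stop("no '", split, "' images under ", data_dir)
  dets <- collect_predictions(model, ds, config)
  gt <- do.call(rbind, lapply(ds, function(a) {
    if (nrow(a$boxes)) cbind(image = a$filename, a$boxes) else NULL
  }))
  rep <- evaluate_detections(
    dets, gt, classes = config$classes,
    iou_match_threshold = config$evaluation$iou_match_threshold,
    score_threshold = config$evaluation$score_threshold)
  if (!is.null(out_csv)) {
    out <- rep
    pct <- c("ap", "ppv", "sensitivity", "specificity")
    out[pct] <- lapply(out[pct], function(v) round(100 * v, 1))
    out$f1 <- round(out$f1, 4)
    utils::write.csv(out, out_csv, row.names = FALSE)
    log_line(quiet, "evaluation report: %s", out_csv)
  }
  rep
}

#' @rdname pipeline
#' @param from_gt classify from the ground-truth annotations instead of
#'   detector predictions (no checkpoint needed).
#' @return `ep_classify`: the per-image section-decision data frame.
#' @export
ep_classify <- function(config = default_pipeline_config(), data_dir,
                        checkpoint_path = NULL, out_csv = NULL,
                        split = "test", from_gt = is.null(checkpoint_path),
                        quiet = FALSE) {
  config <- resolve_config(config)
  ds <- load_dataset(data_dir, split = split)
  if (!length(ds)) stop("no '", split, "' images under ", data_dir)
  det_list <- if (from_gt) {
    dl <- lapply(ds, function(a)
      data.frame(class = a$boxes$class, score = rep(1, nrow(a$boxes))))
    names(dl) <- vapply(ds, `[[`, character(1), "filename")
    dl
  } else {
    model <- load_checkpoint(checkpoint_path,
                             expected_classes = config$classes)
    dets <- collect_predictions(model, ds, config)
    dl <- lapply(ds, function(a) {
      d <- dets[dets$image == a$filename, , drop = FALSE]
      data.frame(class = d$class, score = d$score)
    })
    names(dl) <- vapply(ds, `[[`, character(1), "filename")
    dl
  }
  dec <- classify_sections(det_list,
                           confidence_threshold =
                             config$evaluation$score_threshold,
                           templates = config$sections)
  if (!is.null(out_csv)) {
    utils::write.csv(dec, out_csv, row.names = FALSE)
    log_line(quiet, "section decisions: %s", out_csv)
  }
  dec
}

#' @rdname pipeline
#' @param ratings_csv CSV with columns `image`, `reference`, then one
#'   column of section labels per rater.
#' @param baseline rater column used as the McNemar baseline.
#' @return `ep_compare_raters`: the `rater_comparison` object.
#' @export
ep_compare_raters <- function(ratings_csv, out_csv = NULL, baseline = NULL,
                              quiet = FALSE) {
  d <- utils::read.csv(ratings_csv)
  need <- c("image", "reference")
  if (!all(need %in% names(d)))
    stop("ratings CSV must have 'image' and 'reference' columns")
  raters <- setdiff(names(d), need)
  if (length(raters) < 1L) stop("no rater columns found")
  cmp <- rater_report(stats::setNames(lapply(raters, function(r) d[[r]]),
                                      raters),
                      reference = d$reference, baseline = baseline)
  if (!is.null(out_csv)) {
    m <- cmp$metrics
    rates <- c("sensitivity", "specificity", "ppv", "accuracy")
    m[rates] <- lapply(m[rates], function(v) round(100 * v, 2))
    mc <- cmp$mcnemar
    names(mc) <- c("rater", "section", "b", "c", "p_value", "significant")
    merged <- merge(m, mc, by = c("rater", "section"), all.x = TRUE,
                    sort = FALSE)
    utils::write.csv(merged, out_csv, row.names = FALSE)
    log_line(quiet, "rater comparison: %s", out_csv)
  }
  cmp
}
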