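#' Scaled-down end-to-end benchmark experiment
#'
#' The package's reference experiment: generate a seeded synthetic
#' section dataset on the easy preset (low speckle noise, well-separated
#' structures), train the tiny detector configuration (128 px input,
#' width multiple 0.125) on the training split, and score the held-out
#' split with the full evaluation battery plus section classification
#' from the detector's structure sets.  Problem sizes default to 200
#' training and 50 held-out images (50 per section, 80/20 split).
#'
#' @param seed master seed; data, weight-init and shuffling seeds are
#'   derived from it.
#' @param dir dataset directory (a fresh temporary directory by
#'   default).
#' @param n_per_section images generated per section.
#' @param epochs,lr,batch_size,box_weight training configuration of the
#'   experiment (box weight 0.5 trains box regression at this small
#'   problem scale; classification/objectness weights keep their
#'   defaults).
#' @param quiet suppress progress output.
#' @return a list: `map50` (mAP at IoU 0.5 on the held-out split, as a
#'   fraction), `section_recovery` (fraction of held-out images whose
#'   section label is recovered from the detector's predictions),
#'   `report` (the per-class `eval_report`), `decisions`, `n_train`,
#'   `n_test`, and `model`.
#' @export
run_benchmark_experiment <- function(seed = 1L, dir = NULL,
                                     n_per_section = 50L, epochs = 50L,
                                     lr = 0.05, batch_size = 8L,
                                     box_weight = 0.5, quiet = TRUE) {
  if (is.null(dir)) dir <- tempfile("echoplane_bench")
  cfg <- default_pipeline_config()
  cfg$dataset$n_per_section <- as.integer(n_per_section)
  cfg$dataset$split <- list(train = 0.8, test = 0.2)
  cfg$loss_weights$c <- box_weight
  cfg$train$epochs <- as.integer(epochs)
  cfg$train$lr <- lr
  cfg$train$batch_size <- as.integer(batch_size)
  cfg$seeds <- list(data = as.integer(seed),
                    model = as.integer(seed) + 1L,
                    train = as.integer(seed) + 2L)
  manifest <- ep_generate(cfg, dir, force = TRUE, quiet = quiet)
  ck <- file.path(dir, "checkpoint.rds")
  model <- ep_train(cfg, dir, ck, quiet = quiet)
  rep <- ep_evaluate(cfg, dir, ck, split = "test", quiet = quiet)
  dec <- ep_classify(cfg, dir, checkpoint_path = ck, split = "test",
                     from_gt = FALSE, quiet = quiet)
  truth <- manifest$label[match(dec$image, manifest$filename)]
  list(map50 = rep$ap[rep$class == "All"],
       section_recovery = mean(dec$section == truth),
       report = rep, decisions = dec,
       n_train = sum(manifest$split == "train"),
       n_test = sum(manifest$split == "test"),
       model = model)
}
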