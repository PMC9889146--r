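#' Published benchmark scores shipped with the package
#'
#' Two small reference tables from a clinical fetal-heart structure
#' recognition study, used as arithmetic worked examples for the metric
#' implementations: the per-structure recognition scores (AP, PPV,
#' sensitivity, F1, specificity, in percent except F1) of an
#' SIoU-trained single-stage detector, and a model-comparison table
#' including its plain-IoU-loss baseline.  The F1 column is redundant
#' given PPV and S, and the overall AP is the mean of the per-structure
#' APs -- which is exactly what makes these tables useful consistency
#' checks for [f1()] and [mean_average_precision()].
#'
#' @return a data frame.
#' @export
benchmark_structure_metrics <- function() {
  utils::read.csv(system.file("extdata", "benchmark_structure_metrics.csv",
                              package = "echoplane"))
}

#' @rdname benchmark_structure_metrics
#' @export
benchmark_model_comparison <- function() {
  utils::read.csv(system.file("extdata", "benchmark_model_comparison.csv",
                              package = "echoplane"))
}
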