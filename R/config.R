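#' Pipeline configuration
#'
#' A single YAML-serializable list driving the generate / train /
#' evaluate / classify pipeline.  The schema is strict: unknown keys are
#' rejected at load time, and every run is seeded through the config (no
#' silent entropy).
#'
#' @return the default configuration list (class `pipeline_config`).
#' @export
default_pipeline_config <- function() {
  structure(list(
    classes = structure_classes(),
    sections = section_templates(),
    dataset = list(n_per_section = 50L, size = 128L, noise = 0.08,
                   drop_probability = 0,
                   split = list(train = 0.7, val = 0.15, test = 0.15)),
    model = list(input_size = 128L, width_multiple = 0.125,
                 depth_multiple = 0.33, strides = c(8L, 16L, 32L, 64L),
                 spp_kernels = c(3L, 5L, 7L)),
    loss_weights = list(a = 0.5, b = 1.0, c = 0.05),
    siou = list(theta = 4),
    train = list(epochs = 40L, lr = 0.01, batch_size = 8L, momentum = 0.9,
                 weight_decay = 5e-4, warmup_epochs = 3L),
    evaluation = list(iou_match_threshold = 0.5, score_threshold = 0.25,
                      nms_iou = 0.45),
    seeds = list(data = 1L, model = 7L, train = 42L)
  ), class = "pipeline_config")
}

.config_keys <- list(
  top = c("classes", "sections", "dataset", "model", "loss_weights",
          "siou", "train", "evaluation", "seeds"),
  dataset = c("n_per_section", "size", "noise", "drop_probability", "split"),
  model = c("input_size", "width_multiple", "depth_multiple", "strides",
            "spp_kernels"),
  loss_weights = c("a", "b", "c"),
  siou = "theta",
  train = c("epochs", "lr", "batch_size", "momentum", "weight_decay",
            "warmup_epochs"),
  evaluation = c("iou_match_threshold", "score_threshold", "nms_iou"),
  seeds = c("data", "model", "train")
)

#' @rdname default_pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_pipeline_config(raw)
}

#' @rdname default_pipeline_config
#' @param config a configuration list; partial configs are completed with
#'   defaults before validation.
#' @export
validate_pipeline_config <- function(config) {
  def <- default_pipeline_config()
  unknown <- setdiff(names(config), .config_keys$top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (sec in intersect(names(config), names(.config_keys))) {
    if (sec == "top") next
    bad <- setdiff(names(config[[sec]]), .config_keys[[sec]])
    if (length(bad))
      stop("unknown config key(s) under '", sec, "': ",
           paste(bad, collapse = ", "))
    def[[sec]][names(config[[sec]])] <- config[[sec]]
  }
  if (!is.null(config$classes)) def$classes <- unlist(config$classes)
  if (!is.null(config$sections))
    def$sections <- lapply(config$sections, unlist)
  if (length(def$classes) < 1L) stop("class list must not be empty")
  missing_cls <- setdiff(unique(unlist(def$sections)), def$classes)
  if (length(missing_cls))
    stop("section templates reference unknown classes: ",
         paste(missing_cls, collapse = ", "))
  structure(def, class = "pipeline_config")
}

#' @rdname default_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

as_model_config <- function(config, anchors = NULL) {
  m <- config$model
  model_config(input_size = m$input_size,
               depth_multiple = m$depth_multiple,
               width_multiple = m$width_multiple,
               num_classes = length(config$classes),
               strides = m$strides, anchors = anchors,
               spp_kernels = m$spp_kernels)
}
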