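#' Anatomical structure classes and standard-section templates
#'
#' The detector recognizes ten anatomical structure classes of the fetal
#' heart; five standard screening planes are defined by the set of
#' structures that must be identifiable in the image:
#' \describe{
#'   \item{4CH}{the approximately symmetric four-chamber region (a single
#'     detected class).}
#'   \item{LVOT}{left ventricular outflow tract: LA, LV, RV and AO.}
#'   \item{RVOT}{right ventricular outflow tract: RV, AA and SVC.}
#'   \item{3VV}{three-vessel view: bifurcated PA and AO.}
#'   \item{3VT}{three-vessel-trachea view: AO, MPA, SVC and T.}
#' }
#' An image whose detected structure set fully covers a template is a
#' standard section of that plane; otherwise it is nonstandard.
#'
#' @return `structure_classes()`: the ten class names in file order
#'   (0-based ids in annotation files follow this order).
#'   `section_templates()`: a named list mapping each section id to its
#'   required structure set.
#' @export
structure_classes <- function() {
  c("4CH", "LV", "LA", "AO", "RV", "AA", "SVC", "PA", "MPA", "T")
}

#' @rdname structure_classes
#' @export
section_templates <- function() {
  list(
    "4CH"  = "4CH",
    "LVOT" = c("LA", "LV", "RV", "AO"),
    "RVOT" = c("RV", "AA", "SVC"),
    "3VV"  = c("PA", "AO"),
    "3VT"  = c("AO", "MPA", "SVC", "T")
  )
}

# Tie-break priority when several completed templates have equal size.
.section_priority <- c("4CH", "3VT", "LVOT", "RVOT", "3VV")

#' Required structures of a standard section
#'
#' @param section_id one of `"4CH"`, `"LVOT"`, `"RVOT"`, `"3VV"`, `"3VT"`.
#' @param templates template table, see [section_templates()].
#' @return character vector of required structure class names.
#' @export
required_structures <- function(section_id, templates = section_templates()) {
  if (length(section_id) != 1L || !section_id %in% names(templates))
    stop("unknown section id: ", paste(section_id, collapse = ", "))
  templates[[section_id]]
}

#' Classify an image's section from its detected structures
#'
#' Keeps, per structure class, the highest-scoring detection at or above
#' `confidence_threshold`, then searches the section templates whose
#' required structure set is fully present.  Among completed templates the
#' one with the larger required set wins (more anatomical evidence);
#' remaining ties fall to a fixed priority order (4CH, 3VT, LVOT, RVOT,
#' 3VV).  If no template is complete the image is nonstandard and the
#' best partial match (largest fraction of required structures present,
#' same tie-break) is reported with its missing set.
#'
#' @param detections a data frame with columns `class` (structure name)
#'   and `score` (confidence in `[0, 1]`), e.g. from [predict_image()];
#'   zero rows allowed.
#' @param confidence_threshold minimum score for a detection to count.
#' @param templates template table, see [section_templates()].
#' @return a list of class `section_decision`: `section_id` (or
#'   `"NONSTANDARD"`), `is_standard`, `best_section` (the chosen or best
#'   partial template), `matched_structures`, `missing_structures`, and
#'   `score` (mean confidence of the matched structures, `NA` if none).
#' @export
classify_section <- function(detections, confidence_threshold = 0.25,
                             templates = section_templates()) {
  if (is.null(detections) || nrow(as.data.frame(detections)) == 0L) {
    detections <- data.frame(class = character(), score = numeric())
  }
  detections <- as.data.frame(detections)
  stopifnot(all(c("class", "score") %in% names(detections)))
  keep <- detections$score >= confidence_threshold
  det <- detections[keep, , drop = FALSE]
  # duplicate detections of one class: highest score only
  if (nrow(det)) {
    det <- det[order(-det$score), , drop = FALSE]
    det <- det[!duplicated(det$class), , drop = FALSE]
  }
  present <- det$class

  ord <- names(templates)[order(-lengths(templates),
                                match(names(templates), .section_priority))]
  frac <- vapply(ord, function(s) {
    req <- templates[[s]]
    mean(req %in% present)
  }, numeric(1))
  complete <- frac >= 1
  best <- ord[which.max(frac)]          # first max wins: size then priority
  chosen <- if (any(complete)) ord[which(complete)[1L]] else best

  req <- templates[[chosen]]
  matched <- intersect(req, present)
  missing <- setdiff(req, present)
  structure(list(
    section_id = if (length(missing) == 0L) chosen else "NONSTANDARD",
    is_standard = length(missing) == 0L,
    best_section = chosen,
    matched_structures = matched,
    missing_structures = missing,
    score = if (length(matched)) mean(det$score[det$class %in% matched]) else NA_real_
  ), class = "section_decision")
}

#' @export
print.section_decision <- function(x, ...) {
  cat(sprintf("section: %s (%s)\n", x$section_id,
              if (x$is_standard) "standard" else "nonstandard"))
  if (!x$is_standard)
    cat(sprintf("  best partial: %s, missing: %s\n", x$best_section,
                paste(x$missing_structures, collapse = ", ")))
  invisible(x)
}

#' Batch section classification to a data frame
#'
#' @param detection_list a named list of detection data frames, one per
#'   image.
#' @inheritParams classify_section
#' @return a data frame with one row per image: `image`, `section`,
#'   `is_standard`, `missing_structures` (comma-joined), `score`.
#' @export
classify_sections <- function(detection_list, confidence_threshold = 0.25,
                              templates = section_templates()) {
  rows <- lapply(names(detection_list), function(id) {
    d <- classify_section(detection_list[[id]], confidence_threshold, templates)
    data.frame(image = id, section = d$section_id,
               is_standard = d$is_standard,
               best_section = d$best_section,
               missing_structures = paste(d$missing_structures, collapse = ","),
               score = d$score)
  })
  do.call(rbind, rows)
}
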