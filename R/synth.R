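#' Per-class rendering defaults for the schematic ultrasound generator
#'
#' Each anatomical structure class is drawn as a filled ellipse with a
#' class-specific gray level and size (as a fraction of the image side).
#' Cardiac chambers and the four-chamber region render bright
#' (myocardium-like), vessels and the trachea render dark (anechoic
#' lumen), against a mid-gray speckled tissue background; the gray
#' ladder is spaced so classes stay separable under speckle noise.
#' Purely schematic -- no anatomical-realism claim.
#'
#' @return a data frame with columns `class`, `intensity`, `size_frac`.
#' @export
structure_appearance <- function() {
  data.frame(
    class = c("4CH", "LV", "LA", "RV", "AO", "SVC", "T", "AA", "PA", "MPA"),
    intensity = c(0.97, 0.88, 0.79, 0.70, 0.02, 0.10, 0.18, 0.26, 0.34, 0.42),
    size_frac = c(0.42, 0.20, 0.17, 0.21, 0.15, 0.13, 0.11, 0.16, 0.18, 0.15)
  )
}

# Nominal structure centers per section, as image fractions (x, y).
section_layouts <- function() {
  list(
    "4CH"  = data.frame(class = "4CH", mx = 0.50, my = 0.55),
    "LVOT" = data.frame(class = c("LV", "RV", "LA", "AO"),
                        mx = c(0.36, 0.64, 0.38, 0.64),
                        my = c(0.38, 0.36, 0.66, 0.66)),
    "RVOT" = data.frame(class = c("RV", "AA", "SVC"),
                        mx = c(0.36, 0.60, 0.66),
                        my = c(0.42, 0.62, 0.36)),
    "3VV"  = data.frame(class = c("PA", "AO"),
                        mx = c(0.40, 0.63),
                        my = c(0.52, 0.50)),
    "3VT"  = data.frame(class = c("AO", "MPA", "SVC", "T"),
                        mx = c(0.36, 0.56, 0.68, 0.48),
                        my = c(0.58, 0.38, 0.60, 0.75))
  )
}

#' Scene specification for one synthetic section image
#'
#' Declares everything [generate_image()] needs: the section template,
#' image size, per-structure placement distributions, speckle-noise and
#' blur parameters, transducer fan geometry, and the per-structure drop
#' probability used to produce nonstandard variants.
#'
#' @param section_id one of the five standard section ids.
#' @param size square image side in pixels.
#' @param noise half-width of the multiplicative uniform speckle factor
#'   (`U(1 - noise, 1 + noise)` per pixel).
#' @param blur_sigma Gaussian blur sigma in pixels applied after the
#'   speckle.
#' @param drop_probability probability that a required structure is
#'   omitted (scalar, or a named vector by class); 0 yields standard
#'   sections only.
#' @param pos_sd placement standard deviation of structure centers
#'   (image fractions).
#' @param size_jitter relative standard deviation of structure sizes.
#' @param background tissue gray level inside the fan.
#' @param fan list: `apex_y` (apex y as image fraction, usually
#'   negative), `half_angle` (degrees from vertical), `radius`
#'   (fraction of image side).
#' @return a list of class `scene_spec`.
#' @export
scene_spec <- function(section_id, size = 128L, noise = 0.08,
                       blur_sigma = 0.8, drop_probability = 0,
                       pos_sd = 0.025, size_jitter = 0.08,
                       background = 0.55,
                       fan = list(apex_y = -0.15, half_angle = 35,
                                  radius = 1.2)) {
  layouts <- section_layouts()
  if (!section_id %in% names(layouts))
    stop("unknown section id: ", section_id)
  app <- structure_appearance()
  st <- merge(layouts[[section_id]], app, by = "class", sort = FALSE)
  structure(list(section_id = section_id, size = as.integer(size),
                 structures = st, noise = noise, blur_sigma = blur_sigma,
                 drop_probability = drop_probability, pos_sd = pos_sd,
                 size_jitter = size_jitter, background = background,
                 fan = fan),
            class = "scene_spec")
}

fan_mask <- function(size, fan) {
  x <- matrix(rep(seq_len(size) - 0.5, each = size), size, size)
  y <- matrix(rep(seq_len(size) - 0.5, times = size), size, size)
  ax <- size / 2; ay <- fan$apex_y * size
  dx <- x - ax; dy <- y - ay
  ang <- abs(atan2(dx, dy)) * 180 / pi
  r <- sqrt(dx^2 + dy^2)
  ang <= fan$half_angle & r <= fan$radius * size & r >= 0.22 * size
}

point_in_fan <- function(px, py, size, fan) {
  ax <- size / 2; ay <- fan$apex_y * size
  dx <- px - ax; dy <- py - ay
  ang <- abs(atan2(dx, dy)) * 180 / pi
  r <- sqrt(dx^2 + dy^2)
  ang <= fan$half_angle & r <= fan$radius * size & r >= 0.24 * size
}

gblur_mat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  as.matrix(EBImage::gblur(EBImage::Image(m), sigma = sigma))
}

#' Render one annotated schematic ultrasound image
#'
#' Draws a fan-masked speckle background, places one ellipse per kept
#' structure of the section template (resampling placements that leave
#' the fan or collide with an already placed structure, up to a retry
#' cap), applies multiplicative uniform speckle followed by Gaussian
#' blur, and annotates each ellipse with its tight bounding box.  Fully
#' deterministic given `seed`.
#'
#' @param spec a [scene_spec()].
#' @param seed integer RNG seed.
#' @param keep_masks also return the per-structure binary masks (used by
#'   the tight-box checks).
#' @return a list of class `annotated_image`: `image` (numeric matrix in
#'   `[0, 1]`, rows = image rows), `boxes` (data frame `class`,
#'   `class_id`, `cx`, `cy`, `w`, `h` in pixels), `section` (the template
#'   id), `label` (section decision from the ground-truth structure set),
#'   `is_standard`, `seed`, and optionally `masks`.
#' @export
generate_image <- function(spec, seed = 1L, keep_masks = FALSE) {
  stopifnot(inherits(spec, "scene_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  size <- spec$size
  st <- spec$structures
  dp <- spec$drop_probability
  drop_p <- if (length(dp) == 1L && is.null(names(dp))) {
    rep(dp, nrow(st))
  } else {
    p <- rep(0, nrow(st))
    p[match(names(dp), st$class)] <- dp
    p
  }
  kept <- st[stats::runif(nrow(st)) >= drop_p, , drop = FALSE]

  img <- matrix(spec$background, size, size)
  mask <- fan_mask(size, spec$fan)
  boxes <- list(); masks <- list()
  placed <- NULL
  xg <- matrix(rep(seq_len(size) - 0.5, each = size), size, size)  # cols = x
  yg <- matrix(rep(seq_len(size) - 0.5, times = size), size, size) # rows = y
  for (i in seq_len(nrow(kept))) {
    ok <- FALSE
    for (try in seq_len(100L)) {
      cx <- (kept$mx[i] + stats::rnorm(1, 0, spec$pos_sd)) * size
      cy <- (kept$my[i] + stats::rnorm(1, 0, spec$pos_sd)) * size
      w <- kept$size_frac[i] * size *
        exp(stats::rnorm(1, 0, spec$size_jitter))
      asp <- stats::runif(1, 0.85, 1.2)
      h <- w * asp
      corners <- rbind(c(cx - w / 2, cy - h / 2), c(cx + w / 2, cy - h / 2),
                       c(cx - w / 2, cy + h / 2), c(cx + w / 2, cy + h / 2))
      if (!all(point_in_fan(corners[, 1], corners[, 2], size, spec$fan)))
        next
      cand <- bbox(cx, cy, w, h)
      if (!is.null(placed) &&
          any(box_iou_matrix(cand, placed) > 0.05)) next
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could not place structure ", kept$class[i],
           " inside the fan after 100 attempts")
    placed <- rbind(placed, cand)
    ell <- ((xg - cx) / (w / 2))^2 + ((yg - cy) / (h / 2))^2 <= 1
    img[ell] <- kept$intensity[i]
    boxes[[length(boxes) + 1L]] <- data.frame(
      class = kept$class[i],
      class_id = match(kept$class[i], structure_classes()) - 1L,
      cx = cx, cy = cy, w = w, h = h)
    if (keep_masks) masks[[kept$class[i]]] <- ell
  }
  speckle <- matrix(stats::runif(size * size, 1 - spec$noise,
                                 1 + spec$noise), size, size)
  img <- gblur_mat(img * speckle, spec$blur_sigma)
  img[!mask] <- 0.02
  img <- pmin(pmax(img, 0), 1)

  boxes <- if (length(boxes)) do.call(rbind, boxes) else
    data.frame(class = character(), class_id = integer(), cx = numeric(),
               cy = numeric(), w = numeric(), h = numeric())
  gt_det <- data.frame(class = boxes$class, score = rep(1, nrow(boxes)))
  dec <- classify_section(gt_det, confidence_threshold = 0)
  out <- list(image = img, boxes = boxes, section = spec$section_id,
              label = dec$section_id, is_standard = dec$is_standard,
              seed = seed)
  if (keep_masks) out$masks <- masks
  structure(out, class = "annotated_image")
}

#' Generate an on-disk synthetic section dataset
#'
#' Writes PNG images, darknet-style label files (one line per structure,
#' `class_id cx cy w h` normalized to 6 decimals), a manifest CSV
#' (`filename`, `section`, `label`, `is_standard`, `split`) and a
#' `dataset.yaml` config.  Split sizes follow a floor-then-distribute
#' rule (floors of `n * fraction`, remaining images to the largest
#' fractional remainders in split order); assignment is seeded, disjoint
#' and exhaustive.  Re-running with the same seed reproduces identical
#' files.
#'
#' @param dir output directory (created; must be empty unless
#'   `force = TRUE`).
#' @param specs list of [scene_spec()]s, one per section (default: all
#'   five standard sections at the given size).
#' @param n_per_section images per spec.
#' @param split named fractions summing to 1.
#' @param seed master seed; per-image seeds are drawn from it.
#' @param size image side used for the default specs.
#' @param noise,drop_probability forwarded to the default specs.
#' @param force allow writing into a non-empty directory.
#' @return invisibly, the manifest data frame.
#' @export
generate_dataset <- function(dir, specs = NULL, n_per_section = 20L,
                             split = c(train = 0.7, val = 0.15, test = 0.15),
                             seed = 1L, size = 128L, noise = 0.08,
                             drop_probability = 0, force = FALSE) {
  if (n_per_section < 1L) stop("n_per_section must be at least 1")
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (is.null(names(split)) || any(names(split) == ""))
    stop("split fractions must be named")
  if (is.null(specs))
    specs <- lapply(names(section_layouts()), scene_spec, size = size,
                    noise = noise, drop_probability = drop_probability)
  if (dir.exists(dir) && length(dir(dir)) && !force)
    stop("output directory is not empty (use force = TRUE to overwrite)")
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "labels"), recursive = TRUE, showWarnings = FALSE)

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  n_total <- length(specs) * n_per_section
  img_seeds <- sample.int(.Machine$integer.max %/% 2L, n_total)
  split_id <- split_assign(n_total, split)

  manifest <- vector("list", n_total)
  k <- 0L
  for (sp in specs) {
    for (i in seq_len(n_per_section)) {
      k <- k + 1L
      ann <- generate_image(sp, seed = img_seeds[k])
      stem <- sprintf("%s_%04d", gsub("[^0-9A-Za-z]", "", sp$section_id), i)
      EBImage::writeImage(EBImage::Image(t(ann$image)),
                          file.path(dir, "images", paste0(stem, ".png")))
      write_darknet_labels(ann$boxes, sp$size, sp$size,
                           file.path(dir, "labels", paste0(stem, ".txt")))
      manifest[[k]] <- data.frame(
        filename = paste0(stem, ".png"), section = sp$section_id,
        label = ann$label, is_standard = ann$is_standard,
        split = split_id[k], seed = img_seeds[k])
    }
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(
    classes = structure_classes(),
    sections = section_templates(),
    image_dir = "images", label_dir = "labels",
    manifest = "manifest.csv", image_size = specs[[1]]$size),
    file.path(dir, "dataset.yaml"))
  invisible(manifest)
}

# floor-then-distribute deterministic split sizing + seeded assignment
split_assign <- function(n, split) {
  sizes <- floor(n * split)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- n * split - sizes
    extra <- order(-frac, seq_along(split))[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  pool <- sample.int(n)
  out <- character(n)
  at <- 0L
  for (j in seq_along(sizes)) {
    if (sizes[j] > 0)
      out[pool[at + seq_len(sizes[j])]] <- names(split)[j]
    at <- at + sizes[j]
  }
  out
}

#' Write and read darknet-style label files
#'
#' One line per box: `class_id cx cy w h`, 0-based class id and
#' normalized center-format coordinates printed to 6 decimal places.
#'
#' @param boxes data frame with `class_id`, `cx`, `cy`, `w`, `h` in
#'   pixels.
#' @param width,height image dimensions for normalization.
#' @param path label file path.
#' @export
write_darknet_labels <- function(boxes, width, height, path) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", boxes$class_id,
                   boxes$cx / width, boxes$cy / height,
                   boxes$w / width, boxes$h / height)
  writeLines(lines, path)
}

#' @rdname write_darknet_labels
#' @param class_names class list mapping 0-based ids to names.
#' @return `read_darknet_labels`: a data frame with `class`, `class_id`
#'   and pixel-unit `cx`, `cy`, `w`, `h`.
#' @export
read_darknet_labels <- function(path, width, height,
                                class_names = structure_classes()) {
  if (file.size(path) == 0)
    return(data.frame(class = character(), class_id = integer(),
                      cx = numeric(), cy = numeric(), w = numeric(),
                      h = numeric()))
  d <- utils::read.table(path, col.names = c("class_id", "cx", "cy", "w", "h"))
  data.frame(class = class_names[d$class_id + 1L], class_id = d$class_id,
             cx = d$cx * width, cy = d$cy * height,
             w = d$w * width, h = d$h * height)
}

#' Load a generated dataset from disk
#'
#' @param dir dataset root written by [generate_dataset()].
#' @param split optional split name filter (e.g. `"train"`).
#' @return a list of `annotated_image`-like entries (`image`, `boxes`,
#'   `section`, `label`, `is_standard`, `split`, `filename`).
#' @export
load_dataset <- function(dir, split = NULL) {
  cfgp <- file.path(dir, "dataset.yaml")
  if (!file.exists(cfgp)) stop("no dataset.yaml under ", dir)
  cfg <- yaml::read_yaml(cfgp)
  manifest <- utils::read.csv(file.path(dir, cfg$manifest))
  if (!is.null(split)) manifest <- manifest[manifest$split %in% split, ]
  lapply(seq_len(nrow(manifest)), function(i) {
    f <- manifest$filename[i]
    img <- t(as.matrix(EBImage::readImage(
      file.path(dir, cfg$image_dir, f))))
    lab <- file.path(dir, cfg$label_dir, sub("\\.png$", ".txt", f))
    boxes <- read_darknet_labels(lab, ncol(img), nrow(img),
                                 unlist(cfg$classes))
    list(image = img, boxes = boxes, section = manifest$section[i],
         label = manifest$label[i], is_standard = manifest$is_standard[i],
         split = manifest$split[i], filename = f)
  })
}
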