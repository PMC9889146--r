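#' Axis-aligned bounding boxes in center format
#'
#' Boxes are stored as numeric matrices with columns `cx`, `cy`, `w`, `h`:
#' horizontal/vertical center plus width and height, in pixels or as
#' normalized image fractions.  All geometry in the package (IoU, the SIoU
#' cost terms, target assignment, NMS) works on this representation;
#' corner-format conversion is explicit and exact.
#'
#' @param cx,cy box center coordinates.
#' @param w,h box width and height; must be strictly positive.
#' @return a numeric matrix with one row per box and columns
#'   `cx`, `cy`, `w`, `h`.
#' @examples
#' b <- bbox(cx = 2, cy = 2, w = 4, h = 4)
#' bbox_to_corners(b)
#' @export
bbox <- function(cx, cy, w, h) {
  b <- cbind(cx = as.numeric(cx), cy = as.numeric(cy),
             w = as.numeric(w), h = as.numeric(h))
  validate_bbox(b)
  b
}

#' Coerce to a bounding-box matrix
#'
#' @param x a numeric vector of length 4 (`cx`, `cy`, `w`, `h`), a matrix or
#'   a data frame with those columns.
#' @return a validated box matrix (see [bbox()]).
#' @export
as_bbox <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("cx", "cy", "w", "h")])
  if (is.null(dim(x))) {
    if (length(x) != 4L)
      stop("a single box needs exactly 4 values (cx, cy, w, h)")
    x <- matrix(as.numeric(x), nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 4L) stop("box matrix must have 4 columns (cx, cy, w, h)")
  colnames(x) <- c("cx", "cy", "w", "h")
  storage.mode(x) <- "double"
  validate_bbox(x)
  x
}

validate_bbox <- function(b) {
  if (anyNA(b) || any(!is.finite(b)))
    stop("box coordinates must be finite and non-missing")
  if (any(b[, "w"] <= 0) || any(b[, "h"] <= 0))
    stop("box width and height must be strictly positive")
  invisible(b)
}

#' Convert between center and corner box formats
#'
#' The conversion is exact: `corners_to_bbox(bbox_to_corners(b))`
#' reproduces `b` up to floating-point identity for representable inputs.
#'
#' @param b a box matrix in center format.
#' @return `bbox_to_corners`: a matrix with columns `x1`, `y1`, `x2`, `y2`
#'   (top-left and bottom-right corners).
#' @export
bbox_to_corners <- function(b) {
  b <- as_bbox(b)
  cbind(x1 = b[, "cx"] - b[, "w"] / 2, y1 = b[, "cy"] - b[, "h"] / 2,
        x2 = b[, "cx"] + b[, "w"] / 2, y2 = b[, "cy"] + b[, "h"] / 2)
}

#' @rdname bbox_to_corners
#' @param corners a matrix with columns `x1`, `y1`, `x2`, `y2`.
#' @export
corners_to_bbox <- function(corners) {
  corners <- as.matrix(corners)
  bbox(cx = (corners[, 1] + corners[, 3]) / 2,
       cy = (corners[, 2] + corners[, 4]) / 2,
       w = corners[, 3] - corners[, 1],
       h = corners[, 4] - corners[, 2])
}

#' Intersection-over-union of box pairs
#'
#' The ratio of the overlap area of two axis-aligned boxes to the area of
#' their union.  `box_iou` is elementwise over paired rows (with recycling
#' of a single row); `box_iou_matrix` returns the full n-by-m cross table
#' used by NMS and detection-to-ground-truth matching.
#'
#' @param a,b box matrices in center format, same units.
#' @return IoU values in `[0, 1]`; 0 for disjoint boxes, 1 only for
#'   identical boxes.
#' @export
box_iou <- function(a, b) {
  a <- as_bbox(a); b <- as_bbox(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  if (nrow(a) != nrow(b))
    stop("box_iou needs equal numbers of boxes (or one of them a single box)")
  ca <- bbox_to_corners(a); cb <- bbox_to_corners(b)
  iw <- pmax(0, pmin(ca[, "x2"], cb[, "x2"]) - pmax(ca[, "x1"], cb[, "x1"]))
  ih <- pmax(0, pmin(ca[, "y2"], cb[, "y2"]) - pmax(ca[, "y1"], cb[, "y1"]))
  inter <- iw * ih
  union <- a[, "w"] * a[, "h"] + b[, "w"] * b[, "h"] - inter
  unname(inter / union)
}

#' @rdname box_iou
#' @export
box_iou_matrix <- function(a, b) {
  a <- as_bbox(a); b <- as_bbox(b)
  ca <- bbox_to_corners(a); cb <- bbox_to_corners(b)
  iw <- pmax(0, outer(ca[, "x2"], cb[, "x2"], pmin) -
                outer(ca[, "x1"], cb[, "x1"], pmax))
  ih <- pmax(0, outer(ca[, "y2"], cb[, "y2"], pmin) -
                outer(ca[, "y1"], cb[, "y1"], pmax))
  inter <- iw * ih
  inter / (outer(a[, "w"] * a[, "h"], b[, "w"] * b[, "h"], `+`) - inter)
}

#' Clip boxes to image bounds
#'
#' Clips corner coordinates into `[0, width] x [0, height]` and converts
#' back to center format.  Boxes clipped to zero extent are dropped.
#'
#' @param b box matrix in pixel units.
#' @param width,height image dimensions in pixels.
#' @return a box matrix (possibly with fewer rows); the kept row indices
#'   are attached as attribute `kept`.
#' @export
clip_boxes <- function(b, width, height) {
  co <- bbox_to_corners(b)
  co[, c("x1", "x2")] <- pmin(pmax(co[, c("x1", "x2")], 0), width)
  co[, c("y1", "y2")] <- pmin(pmax(co[, c("y1", "y2")], 0), height)
  keep <- which(co[, "x2"] > co[, "x1"] & co[, "y2"] > co[, "y1"])
  out <- corners_to_bbox(co[keep, , drop = FALSE])
  attr(out, "kept") <- keep
  out
}
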