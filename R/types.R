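#' Polygon annotation of a single cell
#'
#' A closed polygon outlining one fiber or vessel in image pixel coordinates.
#' Coordinates follow the annotation-tool convention: origin at the top-left,
#' x rightward, y downward, and pixel (row r, column c) has its center at the
#' continuous point (x = c, y = r) (0-based). The polygon is implicitly closed
#' by an edge from the last vertex back to the first.
#'
#' @param class_label Character class of the cell, normally `"fiber"` or
#'   `"vessel"`. Other labels are tolerated (readers keep them verbatim).
#' @param vertices Numeric matrix with two columns (x, y) and at least three
#'   rows, or a list of length-2 numeric vectors.
#' @param confidence Optional confidence in \[0, 1\] (NA for ground truth).
#' @return An object of class `polygon_annotation`.
#' @export
polygon_annotation <- function(class_label, vertices, confidence = NA_real_) {
  if (is.list(vertices)) vertices <- do.call(rbind, vertices)
  vertices <- matrix(as.numeric(vertices), ncol = 2,
                     dimnames = list(NULL, c("x", "y")))
  if (nrow(vertices) < 3L)
    stop("polygon_annotation: need >= 3 vertices, got ", nrow(vertices))
  if (anyNA(vertices))
    stop("polygon_annotation: NA/NaN coordinates are not allowed")
  if (!is.na(confidence) && (confidence < 0 || confidence > 1))
    stop("polygon_annotation: confidence must lie in [0, 1]")
  structure(list(class_label = as.character(class_label),
                 vertices = vertices,
                 confidence = as.numeric(confidence)),
            class = "polygon_annotation")
}

#' @export
print.polygon_annotation <- function(x, ...) {
  cat(sprintf("<polygon_annotation: %s, %d vertices%s>\n", x$class_label,
              nrow(x$vertices),
              if (is.na(x$confidence)) "" else
                sprintf(", conf %.2f", x$confidence)))
  invisible(x)
}

#' All annotations of one image
#'
#' @param image_id Unique image identifier (string).
#' @param width_px,height_px Positive integer image dimensions.
#' @param annotations List of [polygon_annotation()] objects.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(image_id, width_px, height_px, annotations = list()) {
  width_px <- as.integer(width_px); height_px <- as.integer(height_px)
  if (width_px < 1L || height_px < 1L)
    stop("annotation_set: image dimensions must be positive")
  stopifnot(all(vapply(annotations, inherits, TRUE, "polygon_annotation")))
  structure(list(image_id = as.character(image_id), width_px = width_px,
                 height_px = height_px, annotations = annotations),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set '%s' %dx%d px, %d annotations>\n", x$image_id,
              x$width_px, x$height_px, length(x$annotations)))
  invisible(x)
}

#' Binary mask of one cell instance
#'
#' The full mask of a single (possibly translucent, possibly overlapping)
#' cell, cropped to its bounding box. `offset` places the crop in the parent
#' image: grid element `[i, j]` covers image pixel
#' (row `offset[1] + i - 1`, col `offset[2] + j - 1`), 0-based. Masks of
#' different instances may overlap freely: each cell keeps its full extent.
#'
#' @param grid Logical or 0/1 matrix with at least one foreground pixel.
#' @param offset Integer (row, col) 0-based offset of `grid[1, 1]` in the
#'   parent image.
#' @param class_label Class of the cell (`"fiber"`/`"vessel"`).
#' @param confidence Optional confidence in \[0, 1\].
#' @param instance_id Optional identifier string.
#' @return An object of class `instance_mask`.
#' @export
instance_mask <- function(grid, offset = c(0L, 0L), class_label = "fiber",
                          confidence = NA_real_, instance_id = NA_character_) {
  grid <- matrix(as.integer(grid != 0), nrow = nrow(grid))
  if (sum(grid) < 1L) stop("instance_mask: grid has no foreground pixel")
  offset <- as.integer(offset)
  if (length(offset) != 2L || any(offset < 0L))
    stop("instance_mask: offset must be two non-negative integers")
  if (!is.na(confidence) && (confidence < 0 || confidence > 1))
    stop("instance_mask: confidence must lie in [0, 1]")
  structure(list(grid = grid, offset = offset,
                 class_label = as.character(class_label),
                 confidence = as.numeric(confidence),
                 instance_id = as.character(instance_id)),
            class = "instance_mask")
}

#' @export
print.instance_mask <- function(x, ...) {
  cat(sprintf("<instance_mask %s: %dx%d at (%d,%d), %d px%s>\n",
              x$class_label, nrow(x$grid), ncol(x$grid), x$offset[1],
              x$offset[2], sum(x$grid),
              if (is.na(x$confidence)) "" else
                sprintf(", conf %.2f", x$confidence)))
  invisible(x)
}

#' Spatial calibration of the microscope image
#'
#' Micrometers per pixel. The default 0.65 corresponds to a 10x objective with
#' a 0.70x C-mount on a typical slide-scanning brightfield setup
#' (0.65 x 0.65 um pixels).
#'
#' @param um_per_px Positive micrometers-per-pixel scale.
#' @return An object of class `calibration`.
#' @export
calibration <- function(um_per_px = 0.65) {
  um_per_px <- as.numeric(um_per_px)
  if (!is.finite(um_per_px) || um_per_px <= 0)
    stop("calibration: um_per_px must be a positive number")
  structure(list(um_per_px = um_per_px), class = "calibration")
}

# bounding box of an instance mask in parent-image 0-based pixel coords:
# c(row_min, row_max, col_min, col_max)
mask_bbox <- function(mask) {
  fg <- which(mask$grid == 1L, arr.ind = TRUE)
  c(mask$offset[1] + min(fg[, 1]) - 1L, mask$offset[1] + max(fg[, 1]) - 1L,
    mask$offset[2] + min(fg[, 2]) - 1L, mask$offset[2] + max(fg[, 2]) - 1L)
}

# crop an instance mask grid to its tight foreground bounding box
tighten_mask <- function(mask) {
  fg <- which(mask$grid == 1L, arr.ind = TRUE)
  r <- range(fg[, 1]); c <- range(fg[, 2])
  mask$offset <- c(mask$offset[1] + r[1] - 1L, mask$offset[2] + c[1] - 1L)
  mask$grid <- mask$grid[r[1]:r[2], c[1]:c[2], drop = FALSE]
  mask
}
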