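#' Exact Euclidean distance transform of an instance mask
#'
#' Each foreground pixel is assigned the exact Euclidean distance from its
#' center to the nearest background pixel center; background pixels get 0.
#' The grid is padded by one background pixel on every side before the
#' transform, so foreground touching the crop edge still receives a finite
#' distance (a single isolated pixel gets 1.0).
#'
#' @param mask An [instance_mask()] (or 0/1 matrix).
#' @return Numeric matrix of distances, same shape as the mask grid.
#' @export
distance_transform <- function(mask) {
  grid <- if (is.matrix(mask)) matrix(as.integer(mask != 0), nrow = nrow(mask))
          else mask$grid
  if (sum(grid) == 0L) stop("empty mask")
  nr <- nrow(grid); nc <- ncol(grid)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- grid
  d2 <- cpp_edt_sq(pad)
  sqrt(d2[2:(nr + 1L), 2:(nc + 1L), drop = FALSE])
}

#' Width of a cell from the distance transform
#'
#' Twice the maximum of the Euclidean distance transform: the deepest
#' foreground pixel sits on the medial axis, and its distance to the nearest
#' background is the half-thickness. The plain doubling slightly
#' overestimates the true pixel width (a band of w rows has max distance
#' (w + 1)/2, giving w + 1); `bias_correction = TRUE` subtracts the extra
#' pixel (2 * max - 1). The default keeps the plain doubling.
#'
#' @param mask An [instance_mask()].
#' @param bias_correction If `TRUE`, return `2 * max(dt) - 1`.
#' @return Width in pixels (float).
#' @export
width_px <- function(mask, bias_correction = FALSE) {
  m <- max(distance_transform(mask))
  if (bias_correction) 2 * m - 1 else 2 * m
}

#' Does an instance touch the image border?
#'
#' TRUE iff any foreground pixel (for masks) or any vertex/edge (for
#' polygons) lies within `margin` pixels of the image border (row 0, row
#' H-1, col 0 or col W-1). Border-touching cells are partially cut by the
#' frame, so their measurements are biased low and are excluded from
#' summaries.
#'
#' @param instance An [instance_mask()] or [polygon_annotation()].
#' @param width_px,height_px Image dimensions.
#' @param margin Border margin in pixels (default 0 = strict touch).
#' @return Logical.
#' @export
touches_border <- function(instance, width_px, height_px, margin = 0L) {
  if (inherits(instance, "polygon_annotation")) {
    v <- instance$vertices
    bb <- c(min(v[, 2]), max(v[, 2]), min(v[, 1]), max(v[, 1]))
  } else {
    bb <- mask_bbox(instance)
  }
  bb[1] <= margin || bb[2] >= height_px - 1L - margin ||
    bb[3] <= margin || bb[4] >= width_px - 1L - margin
}
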