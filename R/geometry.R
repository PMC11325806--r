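#' Shoelace area of a polygon in square pixels
#'
#' Absolute value of the signed (shoelace) area, so the result is independent
#' of vertex orientation. Degenerate (collinear) polygons return 0.
#'
#' @param poly A [polygon_annotation()] or a two-column vertex matrix.
#' @return Area in px^2.
#' @export
polygon_area_px2 <- function(poly) {
  v <- if (inherits(poly, "polygon_annotation")) poly$vertices else poly
  x <- v[, 1]; y <- v[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Vectorized even-odd (ray casting) point-in-polygon test with boundary
# points counted as inside. px/py are pixel-center coordinates.
points_in_polygon <- function(px, py, vx, vy, eps = 1e-9) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # crossing test (half-open in y so shared vertices count once)
    cross <- ((y1 > py) != (y2 > py))
    if (any(cross)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, cross & (px < xint))
    }
    # boundary test: distance from point to segment within eps
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2)) else 0
    ex <- px - (x1 + t * dx); ey <- py - (y1 + t * dy)
    onedge <- onedge | (ex * ex + ey * ey <= eps * eps)
    j <- i
  }
  inside | onedge
}

#' Rasterize a polygon annotation to an instance mask
#'
#' A pixel is foreground iff its center (x = col, y = row, 0-based) lies
#' inside the polygon by the even-odd rule, or exactly on its boundary
#' (boundary pixels are kept -- a deterministic tie-break). Self-intersecting
#' polygons are resolved by the even-odd rule, consistent with the absolute
#' shoelace area. The mask is cropped to the foreground bounding box with the
#' crop offset recorded.
#'
#' @param poly A [polygon_annotation()].
#' @param height_px,width_px Parent image dimensions in pixels.
#' @return An [instance_mask()].
#' @export
rasterize_polygon <- function(poly, height_px, width_px) {
  v <- poly$vertices
  if (polygon_area_px2(v) <= 0)
    stop("degenerate polygon: zero area")
  r0 <- max(0L, floor(min(v[, 2])))
  r1 <- min(height_px - 1L, ceiling(max(v[, 2])))
  c0 <- max(0L, floor(min(v[, 1])))
  c1 <- min(width_px - 1L, ceiling(max(v[, 1])))
  rows <- r0:r1; cols <- c0:c1
  pc <- expand.grid(y = rows, x = cols)
  fg <- points_in_polygon(pc$x, pc$y, v[, 1], v[, 2])
  grid <- matrix(as.integer(fg), nrow = length(rows), ncol = length(cols))
  if (sum(grid) == 0L)
    stop("degenerate polygon: rasterizes to an empty mask")
  tighten_mask(instance_mask(grid, offset = c(r0, c0),
                             class_label = poly$class_label,
                             confidence = poly$confidence))
}
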