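#' Tile a large image into overlapping windows
#'
#' Large slide scans are processed in square tiles rather than resized, which
#' preserves the micrometer calibration. The stride is
#' `floor(tile_px * (1 - overlap_frac))`; the final row/column of windows is
#' shifted inward so no window exceeds the image, and together the windows
#' cover every pixel. When the tile is larger than the image a single
#' full-image window is returned.
#'
#' @param width_px,height_px Image dimensions.
#' @param tile_px Tile side in pixels (>= 64).
#' @param overlap_frac Fractional overlap between neighbouring tiles in
#'   \[0, 1); default 0.1 matches a typical motorized-stage acquisition
#'   overlap.
#' @return Data frame with columns `row0`, `col0`, `rows`, `cols` (0-based
#'   origins), sorted row-major.
#' @export
tile_image <- function(width_px, height_px, tile_px = 1024L,
                       overlap_frac = 0.1) {
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must lie in [0, 1)")
  if (tile_px < 64L) stop("tile_px must be >= 64")
  if (tile_px >= width_px && tile_px >= height_px)
    return(data.frame(row0 = 0L, col0 = 0L,
                      rows = as.integer(height_px),
                      cols = as.integer(width_px)))
  stride <- max(1L, as.integer(floor(tile_px * (1 - overlap_frac))))
  origins <- function(dim) {
    if (tile_px >= dim) return(0L)
    o <- seq.int(0L, dim - tile_px, by = stride)
    if (o[length(o)] != dim - tile_px) o <- c(o, dim - tile_px)
    as.integer(o)
  }
  r0 <- origins(height_px)
  c0 <- origins(width_px)
  g <- expand.grid(col0 = c0, row0 = r0)   # row-major: row varies slowest
  data.frame(row0 = g$row0, col0 = g$col0,
             rows = as.integer(pmin(tile_px, height_px)),
             cols = as.integer(pmin(tile_px, width_px)))
}
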