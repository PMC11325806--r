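#' Thin a mask to a single-pixel-wide skeleton
#'
#' Zhang-Suen iterative thinning run to fixpoint. The skeleton is a subset of
#' the input foreground, preserves the connectivity of each component, and is
#' one pixel wide (no 2x2 all-foreground block survives except where required
#' to keep 8-connectivity at junctions, which the Zhang-Suen rules guarantee
#' against).
#'
#' @param mask An [instance_mask()] (or a plain 0/1 matrix).
#' @return An object of class `skeleton`: list with `grid` (0/1 matrix, same
#'   shape as the input grid), `offset` (parent-frame 0-based offset),
#'   `pixels` (n x 2 matrix of 1-based grid-local row/col), and `endpoints`
#'   (subset of `pixels` with exactly one 8-neighbour).
#' @export
thin_mask <- function(mask) {
  if (is.matrix(mask)) {
    if (sum(mask != 0) == 0L) stop("empty mask")
    mask <- instance_mask(mask)
  }
  if (sum(mask$grid) == 0L) stop("empty mask")
  thinned <- cpp_zhang_suen(mask$grid)
  skeleton_from_grid(thinned, mask$offset)
}

skeleton_from_grid <- function(grid, offset = c(0L, 0L)) {
  pixels <- which(grid == 1L, arr.ind = TRUE)
  colnames(pixels) <- c("row", "col")
  nb <- count_neighbors(grid)
  endpoints <- pixels[nb[pixels] == 1L, , drop = FALSE]
  structure(list(grid = grid, offset = as.integer(offset),
                 pixels = pixels, endpoints = endpoints),
            class = "skeleton")
}

# number of 8-connected foreground neighbours for every cell
count_neighbors <- function(grid) {
  nr <- nrow(grid); nc <- ncol(grid)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- grid
  acc <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    acc <- acc + pad[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  }
  acc
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton: %d pixels, %d endpoints>\n", nrow(x$pixels),
              nrow(x$endpoints)))
  invisible(x)
}
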