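# adjacency list over skeleton pixels (8-connectivity); returns a list of
# integer vectors indexing rows of sk$pixels (sorted for determinism)
skeleton_adjacency <- function(sk) {
  n <- nrow(sk$pixels)
  id <- matrix(0L, nrow(sk$grid), ncol(sk$grid))
  id[sk$pixels] <- seq_len(n)
  nr <- nrow(sk$grid); nc <- ncol(sk$grid)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    r <- sk$pixels[i, 1]; c <- sk$pixels[i, 2]
    rs <- max(1L, r - 1L):min(nr, r + 1L)
    cs <- max(1L, c - 1L):min(nc, c + 1L)
    nb <- id[rs, cs]
    nb <- nb[nb > 0L & nb != i]
    adj[[i]] <- sort(nb)
  }
  adj
}

# BFS from `start`; returns list(dist, parent) with -1 for unreachable
skeleton_bfs <- function(adj, start) {
  n <- length(adj)
  dist <- rep(-1L, n); parent <- rep(0L, n)
  queue <- integer(n); head <- 1L; tail <- 1L
  queue[1L] <- start; dist[start] <- 0L
  while (head <= tail) {
    u <- queue[head]; head <- head + 1L
    for (v in adj[[u]]) {
      if (dist[v] < 0L) {
        dist[v] <- dist[u] + 1L
        parent[v] <- u
        tail <- tail + 1L
        queue[tail] <- v
      }
    }
  }
  list(dist = dist, parent = parent)
}

# farthest reachable pixel from a BFS result, ties broken by smallest
# (row, col) for reproducibility
farthest_pixel <- function(bfs, pixels) {
  m <- max(bfs$dist)
  cand <- which(bfs$dist == m)
  cand[order(pixels[cand, 1], pixels[cand, 2])][1]
}

#' Longest path through a skeleton
#'
#' The path between the two skeleton pixels at maximal 8-connected graph
#' distance. By default this is found with a double breadth-first search
#' (BFS from an arbitrary pixel to its farthest pixel, then BFS again), which
#' is exact on acyclic skeletons and a fast heuristic when the skeleton
#' contains loops (e.g. vessels with perforation plates). `exact = TRUE`
#' runs BFS from every pixel (exhaustive all-pairs), exact on any skeleton
#' but quadratic; intended for skeletons below ~1e4 pixels.
#'
#' On disconnected skeletons the path is found within the component holding
#' the lexicographically first pixel of the largest component.
#'
#' @param sk A `skeleton` from [thin_mask()].
#' @param exact If `TRUE`, use exhaustive all-pairs BFS.
#' @return n x 2 matrix of ordered 1-based grid-local (row, col) pixels;
#'   consecutive rows are 8-adjacent.
#' @export
longest_skeleton_path <- function(sk, exact = FALSE) {
  n <- nrow(sk$pixels)
  if (n == 0L) stop("empty skeleton")
  if (n == 1L) return(sk$pixels[1, , drop = FALSE])
  adj <- skeleton_adjacency(sk)

  # start in the largest connected component (first by pixel order on ties)
  comp_of <- rep(0L, n); ncomp <- 0L
  for (i in seq_len(n)) {
    if (comp_of[i] == 0L) {
      ncomp <- ncomp + 1L
      b <- skeleton_bfs(adj, i)
      comp_of[b$dist >= 0L] <- ncomp
    }
  }
  main <- which.max(tabulate(comp_of))
  members <- which(comp_of == main)

  if (exact) {
    best <- c(-1L, 0L, 0L)  # dist, start, end
    for (s in members) {
      b <- skeleton_bfs(adj, s)
      e <- farthest_pixel(b, sk$pixels)
      if (b$dist[e] > best[1]) best <- c(b$dist[e], s, e)
    }
    b <- skeleton_bfs(adj, best[2])
    return(walk_back(b, best[3], sk$pixels))
  }

  b1 <- skeleton_bfs(adj, members[1])
  a <- farthest_pixel(b1, sk$pixels)
  b2 <- skeleton_bfs(adj, a)
  z <- farthest_pixel(b2, sk$pixels)
  walk_back(b2, z, sk$pixels)
}

walk_back <- function(bfs, end, pixels) {
  idx <- integer(bfs$dist[end] + 1L)
  u <- end
  for (k in rev(seq_along(idx))) {
    idx[k] <- u
    u <- bfs$parent[u]
  }
  path <- pixels[idx, , drop = FALSE]
  # canonical direction: start at the lexicographically smaller endpoint
  n <- nrow(path)
  if (path[n, 1] < path[1, 1] ||
      (path[n, 1] == path[1, 1] && path[n, 2] < path[1, 2]))
    path <- path[n:1, , drop = FALSE]
  path
}

#' Skeleton length in pixels
#'
#' Length of the longest skeleton path. `"pixel_count"` (the default) counts
#' the pixels on the path, mirroring the common sum-over-skeleton practice;
#' `"weighted_path"` sums per-step lengths (1 for axial, sqrt(2) for diagonal
#' steps) and corrects the up-to-29% undercount of diagonals;
#' `"all_pixels"` counts every skeleton pixel including side branches, for
#' comparison with pipelines that do not extract the longest path.
#'
#' @param sk A `skeleton` from [thin_mask()].
#' @param mode `"pixel_count"`, `"weighted_path"` or `"all_pixels"`.
#' @param exact Passed to [longest_skeleton_path()].
#' @return Length in pixels (float).
#' @export
skeleton_length_px <- function(sk, mode = c("pixel_count", "weighted_path",
                                            "all_pixels"),
                               exact = FALSE) {
  mode <- match.arg(mode)
  if (mode == "all_pixels") return(as.numeric(nrow(sk$pixels)))
  path <- longest_skeleton_path(sk, exact = exact)
  if (mode == "pixel_count") return(as.numeric(nrow(path)))
  if (nrow(path) == 1L) return(1.0)
  steps <- abs(diff(path))
  sum(ifelse(rowSums(steps) == 2L, sqrt(2), 1))
}
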