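# Independent reference implementations used as oracles. These deliberately
# use naive per-pixel loops, separate from the package's vectorized /
# compiled code paths.

# Zhang-Suen thinning, literal published rules, plain R loops.
ref_zhang_suen <- function(grid) {
  img <- grid
  at <- function(r, c) {
    if (r < 1 || r > nrow(img) || c < 1 || c > ncol(img)) 0L else img[r, c]
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      kill <- NULL
      for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
        if (!img[r, c]) next
        p <- c(at(r - 1, c), at(r - 1, c + 1), at(r, c + 1), at(r + 1, c + 1),
               at(r + 1, c), at(r + 1, c - 1), at(r, c - 1), at(r - 1, c - 1))
        B <- sum(p)
        if (B < 2 || B > 6) next
        s <- c(p, p[1])
        A <- sum(s[-length(s)] == 0 & s[-1] == 1)
        if (A != 1) next
        if (step == 1) {
          if (p[1] * p[3] * p[5] != 0 || p[3] * p[5] * p[7] != 0) next
        } else {
          if (p[1] * p[3] * p[7] != 0 || p[1] * p[5] * p[7] != 0) next
        }
        kill <- rbind(kill, c(r, c))
      }
      if (!is.null(kill)) {
        changed <- TRUE
        img[kill] <- 0L
      }
    }
    if (!changed) break
  }
  img
}

# Brute-force exact Euclidean distance transform (1-px background pad).
ref_distance_transform <- function(grid) {
  nr <- nrow(grid); nc <- ncol(grid)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- grid
  bg <- which(pad == 0L, arr.ind = TRUE)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (grid[r, c] == 1L)
      out[r, c] <- sqrt(min((bg[, 1] - (r + 1))^2 + (bg[, 2] - (c + 1))^2))
  }
  out
}

# Scalar crossing-number point-in-polygon (boundary counts as inside).
ref_point_in_polygon <- function(px, py, vx, vy, eps = 1e-9) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    if ((y1 > py) != (y2 > py)) {
      if (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1)) inside <- !inside
    }
    dx <- x2 - x1; dy <- y2 - y1
    l2 <- dx^2 + dy^2
    t <- if (l2 > 0) min(1, max(0, ((px - x1) * dx + (py - y1) * dy) / l2)) else 0
    if ((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2 <= eps^2)
      return(TRUE)
    j <- i
  }
  inside
}

# Foreground pixel count of a polygon by brute-force even-odd test over all
# pixel centers of the frame.
ref_rasterize_count <- function(vx, vy, height_px, width_px) {
  count <- 0L
  for (r in 0:(height_px - 1L)) for (c in 0:(width_px - 1L)) {
    if (ref_point_in_polygon(c, r, vx, vy)) count <- count + 1L
  }
  count
}

# All-pairs longest shortest path over a skeleton's 8-connected pixel graph
# via igraph (independent of the package's double BFS).
ref_longest_path_length <- function(sk) {
  px <- sk$pixels
  n <- nrow(px)
  if (n == 1L) return(1L)
  edges <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (max(abs(px[i, ] - px[j, ])) <= 1L) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  d <- igraph::distances(g)
  d[is.infinite(d)] <- -1
  max(d) + 1  # path length in pixels
}

# Greedy confidence-ordered matcher, re-implemented naively.
ref_greedy_match <- function(preds, gts, thr) {
  conf <- vapply(preds, `[[`, 0, "confidence")
  ids <- vapply(preds, `[[`, "", "instance_id")
  ord <- order(-conf, ids)
  taken <- rep(FALSE, length(gts))
  tp <- 0L
  for (i in ord) {
    best <- 0; bj <- NA
    for (j in seq_along(gts)) {
      if (taken[j]) next
      if (gts[[j]]$class_label != preds[[i]]$class_label) next
      iou <- mask_iou(preds[[i]], gts[[j]])
      if (iou >= thr && iou > best) { best <- iou; bj <- j }
    }
    if (!is.na(bj)) { taken[bj] <- TRUE; tp <- tp + 1L }
  }
  list(tp = tp, fp = length(preds) - tp, fn = sum(!taken))
}

# small helpers for constructing fixtures -----------------------------------

square_mask <- function(side, offset = c(0L, 0L), class_label = "fiber",
                        confidence = NA_real_, instance_id = "m") {
  instance_mask(matrix(1L, side, side), offset = offset,
                class_label = class_label, confidence = confidence,
                instance_id = instance_id)
}

# random 8-connected blob grown from a seed pixel (reproducible)
random_blob <- function(nr, nc, n_px, seed) {
  set.seed(seed)
  g <- matrix(0L, nr, nc)
  r <- sample(2:(nr - 1), 1); c <- sample(2:(nc - 1), 1)
  g[r, c] <- 1L
  placed <- 1L
  while (placed < n_px) {
    fg <- which(g == 1L, arr.ind = TRUE)
    k <- fg[sample(nrow(fg), 1), ]
    dr <- sample(-1:1, 1); dc <- sample(-1:1, 1)
    nr2 <- k[1] + dr; nc2 <- k[2] + dc
    if (nr2 >= 1 && nr2 <= nr && nc2 >= 1 && nc2 <= nc && g[nr2, nc2] == 0L) {
      g[nr2, nc2] <- 1L
      placed <- placed + 1L
    }
  }
  g
}

flood_connected <- function(grid) {
  fg <- which(grid == 1L, arr.ind = TRUE)
  if (nrow(fg) == 0L) return(TRUE)
  seen <- matrix(FALSE, nrow(grid), ncol(grid))
  queue <- list(fg[1, ])
  seen[fg[1, 1], fg[1, 2]] <- TRUE
  while (length(queue) > 0L) {
    p <- queue[[1]]; queue <- queue[-1]
    for (dr in -1:1) for (dc in -1:1) {
      r <- p[1] + dr; c <- p[2] + dc
      if (r >= 1 && r <= nrow(grid) && c >= 1 && c <= ncol(grid) &&
          grid[r, c] == 1L && !seen[r, c]) {
        seen[r, c] <- TRUE
        queue[[length(queue) + 1L]] <- c(r, c)
      }
    }
  }
  sum(seen) == sum(grid)
}
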