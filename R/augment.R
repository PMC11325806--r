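#' Geometric augmentation of an annotation set
#'
#' Applies one exact affine transform to all polygon vertices and updates the
#' image dimensions. Transforms mirror the usual training-time augmentations
#' (rotation by multiples of 90 degrees, horizontal/vertical flips, uniform
#' scaling). Every op is invertible on vertices: applying an op and then its
#' inverse restores coordinates to within 1e-9.
#'
#' Conventions (x rightward, y downward, image W x H):
#' * `fliph`:  (x, y) -> (W - x, y)
#' * `flipv`:  (x, y) -> (x, H - y)
#' * `rot90`:  (x, y) -> (H - y, x), dims swap (clockwise)
#' * `rot180`: (x, y) -> (W - x, H - y)
#' * `rot270`: (x, y) -> (y, W - x), dims swap
#' * `scale`:  (x, y) -> (s x, s y), dims rounded
#'
#' @param set An [annotation_set()].
#' @param op One of `"rot90"`, `"rot180"`, `"rot270"`, `"fliph"`, `"flipv"`,
#'   `"scale"`.
#' @param scale Scale factor in \[0.5, 2\], required when `op == "scale"`.
#' @return The transformed [annotation_set()].
#' @export
augment <- function(set, op, scale = NULL) {
  W <- set$width_px; H <- set$height_px
  tf <- switch(op,
    fliph  = list(f = function(v) cbind(W - v[, 1], v[, 2]), W = W, H = H),
    flipv  = list(f = function(v) cbind(v[, 1], H - v[, 2]), W = W, H = H),
    rot90  = list(f = function(v) cbind(H - v[, 2], v[, 1]), W = H, H = W),
    rot180 = list(f = function(v) cbind(W - v[, 1], H - v[, 2]), W = W, H = H),
    rot270 = list(f = function(v) cbind(v[, 2], W - v[, 1]), W = H, H = W),
    scale  = {
      if (is.null(scale) || scale < 0.5 || scale > 2)
        stop("scale factor must be given in [0.5, 2]")
      s <- scale
      list(f = function(v) v * s,
           W = as.integer(round(W * s)), H = as.integer(round(H * s)))
    },
    stop("unknown augmentation op: ", op))
  anns <- lapply(set$annotations, function(a) {
    polygon_annotation(a$class_label, tf$f(a$vertices), a$confidence)
  })
  annotation_set(set$image_id, tf$W, tf$H, anns)
}

#' Random train/validation split of image ids
#'
#' Deterministic given the seed; the two sets are disjoint and their union is
#' the input. The train size is `round(train_frac * N)`, so e.g. 100 ids at
#' 0.85 give an 85/15 split.
#'
#' @param image_ids Character vector of ids (N >= 2).
#' @param train_frac Training fraction in (0, 1); default 0.85.
#' @param seed Integer RNG seed.
#' @return List with elements `train` and `val`.
#' @export
split_manifest <- function(image_ids, train_frac = 0.85, seed = 1L) {
  n <- length(image_ids)
  if (n < 2L) stop("need at least 2 image ids to split")
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must lie in (0, 1)")
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- min(n - 1L, max(1L, as.integer(round(train_frac * n))))
  list(train = image_ids[sort(perm[seq_len(n_train)])],
       val = image_ids[sort(perm[seq.int(n_train + 1L, n)])])
}

#' Write a split manifest to plain-text files
#'
#' @param split List with `train` and `val` (from [split_manifest()]).
#' @param dir Output directory; writes `train.txt` and `val.txt`, one id per
#'   line.
#' @return `dir`, invisibly.
#' @export
write_split_manifest <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(split$train, file.path(dir, "train.txt"))
  writeLines(split$val, file.path(dir, "val.txt"))
  invisible(dir)
}
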