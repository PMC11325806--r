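#' Specification of a synthetic macerated-slide scene
#'
#' Parameters of the seeded generator. Defaults emulate a single 1920 x 1440
#' brightfield field of view of a safranin-stained hardwood macerate at
#' 0.65 um/px: a handful of long thin fibers and one shorter, wider vessel.
#' Length distributions are log-normal (parametrized by natural-scale mean
#' and sd), widths are normal truncated at 3 px. The fiber defaults
#' (length mean 460 px ~ 300 um, width mean 35 px ~ 23 um) and vessel
#' defaults (length 380 px ~ 247 um, width 78 px ~ 51 um) are scaled from
#' typical aspen macerate measurements at 0.65 um/px.
#'
#' @param width_px,height_px Scene dimensions (>= 256).
#' @param n_fibers,n_vessels Instance counts (>= 0).
#' @param fiber_length_px,vessel_length_px c(mean, sd) of the log-normal
#'   centerline length, px.
#' @param fiber_width_px,vessel_width_px c(mean, sd) of the truncated-normal
#'   width, px.
#' @param curvature Maximum perpendicular bow of the centerline as a
#'   fraction of its length, in \[0, 0.3\].
#' @param absorbance Named per-class optical absorbance in (0, 1]; overlaps
#'   multiply transmittance (Beer-Lambert), so doubly covered pixels are
#'   darker.
#' @param noise_sd Grayscale Gaussian noise sd (image in \[0, 1\]).
#' @param seed Integer seed; scenes are reproducible byte-identically from
#'   (spec, seed).
#' @param allow_border If TRUE, placement rejection is disabled and cells may
#'   touch or cross the frame (for border-exclusion test cases).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width_px = 1920L, height_px = 1440L,
                       n_fibers = 6L, n_vessels = 1L,
                       fiber_length_px = c(460, 120),
                       fiber_width_px = c(35, 5),
                       vessel_length_px = c(380, 80),
                       vessel_width_px = c(78, 8),
                       curvature = 0.15,
                       absorbance = c(fiber = 0.35, vessel = 0.55),
                       noise_sd = 0.02, seed = 1L,
                       allow_border = FALSE) {
  if (width_px < 256L || height_px < 256L)
    stop("scene dimensions must be >= 256 px")
  if (n_fibers < 0L || n_vessels < 0L) stop("instance counts must be >= 0")
  if (curvature < 0 || curvature > 0.3)
    stop("curvature must lie in [0, 0.3]")
  for (p in list(fiber_length_px, fiber_width_px, vessel_length_px,
                 vessel_width_px))
    if (any(p <= 0)) stop("distribution parameters must be positive")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 n_fibers = as.integer(n_fibers),
                 n_vessels = as.integer(n_vessels),
                 fiber_length_px = fiber_length_px,
                 fiber_width_px = fiber_width_px,
                 vessel_length_px = vessel_length_px,
                 vessel_width_px = vessel_width_px,
                 curvature = curvature, absorbance = absorbance,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 allow_border = isTRUE(allow_border)),
            class = "scene_spec")
}

# log-normal meanlog/sdlog from natural-scale mean and sd
lnorm_pars <- function(mean, sd) {
  sdlog <- sqrt(log1p((sd / mean)^2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Draw centerline lengths for a class
#'
#' Log-normal draws on the natural scale of the spec's (mean, sd), floored
#' at 10 px. Used by the generator and by statistical harnesses that need
#' cohorts of lengths without rendering.
#'
#' @param n Number of draws.
#' @param length_pars c(mean, sd) on the natural scale.
#' @return Numeric vector of lengths in px.
#' @export
sample_lengths <- function(n, length_pars) {
  p <- lnorm_pars(length_pars[1], length_pars[2])
  pmax(10, stats::rlnorm(n, p["meanlog"], p["sdlog"]))
}

sample_width <- function(width_pars) {
  w <- stats::rnorm(1, width_pars[1], width_pars[2])
  while (w < 3) w <- stats::rnorm(1, width_pars[1], width_pars[2])
  w
}

#' Arc length of a polyline
#'
#' @param pts n x 2 matrix of (x, y) points.
#' @return Total Euclidean arc length.
#' @export
polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

quad_bezier <- function(p0, p1, p2, n) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2])
}

#' Sample a curved centerline inside given bounds
#'
#' A quadratic Bezier whose control point is offset perpendicular to the
#' chord by up to `curvature * length_px`; the chord is solved numerically so
#' the discretized arc length matches `length_px` within 2%. The curve is
#' discretized at steps of at most 0.5 px, placed at a uniformly random
#' position and orientation, and rejected (up to `max_attempts` times) until
#' every point lies at least `margin` px inside the bounds. Uses the current
#' R RNG stream.
#'
#' @param length_px Requested arc length (>= 10).
#' @param curvature Bow fraction in \[0, 0.3\].
#' @param bounds c(width_px, height_px) of the scene.
#' @param margin Clearance from the frame required for every point.
#' @param max_attempts Placement attempts before failing.
#' @return n x 2 matrix of (x, y) points.
#' @export
sample_centerline <- function(length_px, curvature, bounds, margin = 0,
                              max_attempts = 100L) {
  if (length_px < 10) stop("length_px must be >= 10")
  W <- bounds[1]; H <- bounds[2]
  npt <- max(16L, ceiling(length_px / 0.4))
  for (attempt in seq_len(max_attempts)) {
    h <- stats::runif(1, -1, 1) * curvature * length_px
    arc_of <- function(chord)
      polyline_length(quad_bezier(c(0, 0), c(chord / 2, h), c(chord, 0), npt))
    chord <- if (abs(h) < 1e-9) length_px else
      stats::uniroot(function(ch) arc_of(ch) - length_px,
                     lower = length_px * 0.05, upper = length_px,
                     extendInt = "upX", tol = 1e-6)$root
    pts <- quad_bezier(c(0, 0), c(chord / 2, h), c(chord, 0), npt)
    theta <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    pts <- pts %*% t(R)
    lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
    span <- hi - lo
    free_x <- (W - 1 - 2 * margin) - span[1]
    free_y <- (H - 1 - 2 * margin) - span[2]
    if (free_x < 0 || free_y < 0) next
    shift <- c(margin - lo[1] + stats::runif(1, 0, free_x),
               margin - lo[2] + stats::runif(1, 0, free_y))
    pts <- sweep(pts, 2, shift, "+")
    colnames(pts) <- c("x", "y")
    return(pts)
  }
  stop("scene too crowded: could not place a centerline after ",
       max_attempts, " attempts")
}

# stadium outline polygon: centerline offset by +/- w/2 with semicircle caps
stadium_outline <- function(centerline, width, class_label) {
  hw <- width / 2
  n <- nrow(centerline)
  if (n == 1L) {
    ang <- seq(0, 2 * pi, length.out = 17L)[-17L]
    v <- cbind(centerline[1, 1] + hw * cos(ang),
               centerline[1, 2] + hw * sin(ang))
    return(polygon_annotation(class_label, v))
  }
  step <- max(1L, floor(n / max(8L, ceiling(polyline_length(centerline) / 2))))
  idx <- unique(c(seq(1L, n, by = step), n))
  p <- centerline[idx, , drop = FALSE]
  m <- nrow(p)
  tg <- matrix(0, m, 2)
  tg[1, ] <- p[2, ] - p[1, ]
  tg[m, ] <- p[m, ] - p[m - 1, ]
  if (m > 2) tg[2:(m - 1), ] <- p[3:m, , drop = FALSE] - p[1:(m - 2), , drop = FALSE]
  tg <- tg / sqrt(rowSums(tg^2))
  nrm <- cbind(-tg[, 2], tg[, 1])
  left <- p + hw * nrm
  right <- p - hw * nrm
  cap <- function(center, nhat, that, k = 8L) {
    phi <- seq(0, pi, length.out = k + 2L)[2:(k + 1L)]
    t(vapply(phi, function(a)
      center + hw * (cos(a) * nhat + sin(a) * that), numeric(2)))
  }
  v <- rbind(left,
             cap(p[m, ], nrm[m, ], tg[m, ]),
             right[m:1, , drop = FALSE],
             cap(p[1, ], -nrm[1, ], -tg[1, ]))
  polygon_annotation(class_label, v)
}

#' Rasterize a constant-width sweep of a centerline
#'
#' The full (un-occluded) mask of one synthetic cell: every pixel whose
#' center lies within `width / 2` of the centerline polyline (exact
#' point-to-segment distance), plus the analytic stadium outline polygon.
#'
#' @param centerline n x 2 (x, y) polyline.
#' @param width Cell width in px (>= 3).
#' @param class_label Class recorded on mask and outline.
#' @param frame Optional c(width_px, height_px); when given, the mask is
#'   clipped to the frame.
#' @return List with `mask` (an [instance_mask()]) and `outline`
#'   (a [polygon_annotation()]).
#' @export
render_instance <- function(centerline, width, class_label = "fiber",
                            frame = NULL) {
  if (width < 3) stop("width must be >= 3 px")
  hw <- width / 2
  if (!is.matrix(centerline)) centerline <- matrix(centerline, ncol = 2)
  r0 <- floor(min(centerline[, 2]) - hw) - 1L
  r1 <- ceiling(max(centerline[, 2]) + hw) + 1L
  c0 <- floor(min(centerline[, 1]) - hw) - 1L
  c1 <- ceiling(max(centerline[, 1]) + hw) + 1L
  if (!is.null(frame)) {
    r0 <- max(r0, 0L); c0 <- max(c0, 0L)
    r1 <- min(r1, frame[2] - 1L); c1 <- min(c1, frame[1] - 1L)
  } else {
    r0 <- max(r0, 0L); c0 <- max(c0, 0L)
  }
  grid <- cpp_stadium_mask(centerline[, 1], centerline[, 2], hw,
                           as.integer(r0), as.integer(c0),
                           as.integer(r1 - r0 + 1L),
                           as.integer(c1 - c0 + 1L))
  mask <- tighten_mask(instance_mask(grid, offset = c(r0, c0),
                                     class_label = class_label))
  list(mask = mask,
       outline = stadium_outline(centerline, width, class_label))
}

#' Render a full synthetic macerate scene
#'
#' Places `n_fibers + n_vessels` cells with sampled lengths, widths and
#' curvatures, renders each full mask independently (overlap never clips a
#' mask), and composites a brightfield image: background transmittance 0.92
#' of full scale, each covering instance multiplying the transmitted light by
#' `exp(-absorbance)` per channel with a class stain tint, plus per-pixel
#' Gaussian noise. Identical (spec, seed) give byte-identical scenes.
#'
#' @param spec A [scene_spec()].
#' @param render_image If FALSE, skip image compositing (ground truth and
#'   masks are generated identically); useful for purely statistical
#'   harnesses on large scenes.
#' @return Object of class `synthetic_scene`: list with `image` (H x W x 3
#'   array in \[0, 1\], or NULL), `instances` (list of ground-truth
#'   instances: instance_id, class_label, centerline, true_length_px,
#'   true_width_px, true_area_px2, mask, outline), and `spec`.
#' @export
render_scene <- function(spec, render_image = TRUE) {
  set.seed(spec$seed)
  classes <- c(rep("fiber", spec$n_fibers), rep("vessel", spec$n_vessels))
  instances <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    cls <- classes[i]
    len <- sample_lengths(1L, spec[[paste0(cls, "_length_px")]])
    wid <- sample_width(spec[[paste0(cls, "_width_px")]])
    margin <- if (spec$allow_border) -wid else wid / 2 + 2
    cl <- sample_centerline(len, spec$curvature,
                            c(spec$width_px, spec$height_px), margin)
    ri <- render_instance(cl, wid, cls,
                          frame = c(spec$width_px, spec$height_px))
    instances[[i]] <- list(
      instance_id = sprintf("syn_%03d", i),
      class_label = cls,
      centerline = cl,
      true_length_px = polyline_length(cl),
      true_width_px = wid,
      true_area_px2 = polyline_length(cl) * wid + pi * (wid / 2)^2,
      mask = instances_id_mask(ri$mask, sprintf("syn_%03d", i)),
      outline = ri$outline)
  }
  image <- NULL
  if (render_image) {
    H <- spec$height_px; W <- spec$width_px
    depth <- matrix(0, H, W)
    tint <- list(fiber = c(0.55, 1.35, 1.10),   # safranin: red passes
                 vessel = c(0.65, 1.25, 1.20))
    chan <- array(0, c(H, W, 3))
    for (inst in instances) {
      m <- inst$mask
      a <- spec$absorbance[[inst$class_label]]
      rows <- m$offset[1] + seq_len(nrow(m$grid))
      cols <- m$offset[2] + seq_len(ncol(m$grid))
      tt <- tint[[inst$class_label]]
      for (ch in 1:3)
        chan[rows, cols, ch] <- chan[rows, cols, ch] + m$grid * a * tt[ch]
    }
    image <- array(0, c(H, W, 3))
    for (ch in 1:3)
      image[, , ch] <- 0.92 * exp(-chan[, , ch])
    if (spec$noise_sd > 0)
      image <- image + stats::rnorm(length(image), 0, spec$noise_sd)
    image[image < 0] <- 0
    image[image > 1] <- 1
  }
  structure(list(image = image, instances = instances, spec = spec),
            class = "synthetic_scene")
}

instances_id_mask <- function(mask, id) { mask$instance_id <- id; mask }

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene %dx%d px, %d instances (%d fibers, %d vessels)%s>\n",
              x$spec$width_px, x$spec$height_px, length(x$instances),
              x$spec$n_fibers, x$spec$n_vessels,
              if (is.null(x$image)) ", no image" else ""))
  invisible(x)
}

#' Export a synthetic scene bundle
#'
#' Writes the scene image PNG (when rendered), one full-frame mask PNG per
#' instance, a VGG Image Annotator JSON of the outline polygons, a
#' ground-truth CSV (instance_id, class, true_length_px, true_width_px,
#' true_area_px2) and a centerline CSV (instance_id, x, y). The bundle
#' re-imports through [read_vgg_json()] / [read_instance_masks()].
#'
#' @param scene A `synthetic_scene`.
#' @param dir Output directory.
#' @param image_id Base name for all files (default "scene").
#' @return Named list of written paths, invisibly.
#' @export
export_scene <- function(scene, dir, image_id = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  if (!is.null(scene$image)) {
    paths$image <- file.path(dir, paste0(image_id, ".png"))
    png::writePNG(scene$image, paths$image)
  }
  masks <- lapply(scene$instances, `[[`, "mask")
  write_instance_masks(masks, dir, image_id,
                       scene$spec$width_px, scene$spec$height_px)
  paths$masks_dir <- dir
  outlines <- lapply(scene$instances, `[[`, "outline")
  aset <- annotation_set(image_id, scene$spec$width_px, scene$spec$height_px,
                         outlines)
  paths$annotations <- file.path(dir, paste0(image_id, "_annotations.json"))
  write_vgg_json(aset, paths$annotations)
  truth <- do.call(rbind, lapply(scene$instances, function(i)
    data.frame(instance_id = i$instance_id, class = i$class_label,
               true_length_px = i$true_length_px,
               true_width_px = i$true_width_px,
               true_area_px2 = i$true_area_px2, stringsAsFactors = FALSE)))
  paths$truth <- file.path(dir, paste0(image_id, "_truth.csv"))
  utils::write.csv(truth, paths$truth, row.names = FALSE)
  cl <- do.call(rbind, lapply(scene$instances, function(i)
    data.frame(instance_id = i$instance_id, x = i$centerline[, 1],
               y = i$centerline[, 2], stringsAsFactors = FALSE)))
  paths$centerlines <- file.path(dir, paste0(image_id, "_centerlines.csv"))
  utils::write.csv(cl, paths$centerlines, row.names = FALSE)
  invisible(paths)
}
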