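#' Write per-instance mask PNGs
#'
#' One 8-bit grayscale PNG per instance (0 = background, 255 = foreground),
#' full image frame, named `{image_id}_{idx}_{class}.png`, plus a sidecar CSV
#' `{image_id}_instances.csv` with columns instance_id, file, class,
#' confidence. Overlapping instances simply produce overlapping foreground in
#' their separate files.
#'
#' @param masks List of [instance_mask()] objects.
#' @param dir Output directory (created if missing).
#' @param image_id Image identifier used in file names.
#' @param width_px,height_px Parent image dimensions.
#' @return Data frame of the sidecar table, invisibly.
#' @export
write_instance_masks <- function(masks, dir, image_id, width_px, height_px) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    full <- matrix(0, nrow = height_px, ncol = width_px)
    nr <- nrow(m$grid); nc <- ncol(m$grid)
    full[m$offset[1] + seq_len(nr), m$offset[2] + seq_len(nc)] <- m$grid
    fn <- sprintf("%s_%d_%s.png", image_id, i, m$class_label)
    png::writePNG(full, file.path(dir, fn))
    data.frame(instance_id = if (is.na(m$instance_id))
                 sprintf("%s_%d", image_id, i) else m$instance_id,
               file = fn, class = m$class_label,
               confidence = m$confidence, stringsAsFactors = FALSE)
  })
  sidecar <- do.call(rbind, rows)
  utils::write.csv(sidecar, file.path(dir, sprintf("%s_instances.csv", image_id)),
                   row.names = FALSE)
  invisible(sidecar)
}

#' Read per-instance mask PNGs
#'
#' Reads masks written by [write_instance_masks()] (or any backend following
#' the `{image_id}_{idx}_{class}.png` convention). When the sidecar CSV is
#' present, instance ids and confidences are taken from it.
#'
#' @param dir Directory holding the PNGs.
#' @param image_id Image identifier to read.
#' @return List of [instance_mask()] objects (cropped to bounding boxes),
#'   with attribute `"image_dim"` = c(height, width).
#' @export
read_instance_masks <- function(dir, image_id) {
  files <- list.files(dir, pattern = sprintf("^%s_\\d+_.+\\.png$", image_id))
  if (length(files) == 0L)
    stop("no instance masks for image '", image_id, "' in ", dir)
  idx <- as.integer(sub(sprintf("^%s_(\\d+)_.+$", image_id), "\\1", files))
  files <- files[order(idx)]
  sidecar_path <- file.path(dir, sprintf("%s_instances.csv", image_id))
  sidecar <- if (file.exists(sidecar_path))
    utils::read.csv(sidecar_path, stringsAsFactors = FALSE) else NULL
  dim_seen <- NULL
  masks <- lapply(files, function(fn) {
    img <- png::readPNG(file.path(dir, fn))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    dim_seen <<- dim(img)
    cls <- sub(sprintf("^%s_\\d+_(.+)\\.png$", image_id), "\\1", fn)
    conf <- NA_real_
    iid <- sub("\\.png$", "", fn)
    if (!is.null(sidecar)) {
      row <- sidecar[sidecar$file == fn, ]
      if (nrow(row) == 1L) {
        conf <- row$confidence
        iid <- row$instance_id
      }
    }
    tighten_mask(instance_mask(img > 0.5, offset = c(0L, 0L),
                               class_label = cls, confidence = conf,
                               instance_id = iid))
  })
  attr(masks, "image_dim") <- dim_seen
  masks
}
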