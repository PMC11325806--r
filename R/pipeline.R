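#' Pipeline configuration
#'
#' Defaults: 1024 px tiles with 10% overlap (matching a motorized-stage
#' acquisition), cross-tile duplicate threshold 0.8 IoU (distinct overlapping
#' cells rarely exceed 0.5 IoU while duplicate detections of one cell exceed
#' 0.9), confidence floor 0.25, calibration 0.65 um/px.
#'
#' @param um_per_px Micrometers per pixel.
#' @param tile_px Tile side (>= 256).
#' @param tile_overlap Tile overlap fraction in \[0, 1).
#' @param iou_dedup_threshold Cross-tile duplicate IoU threshold in (0, 1].
#' @param confidence_floor Minimum prediction confidence kept, in (0, 1].
#' @param length_mode Skeleton length mode (see [skeleton_length_px()]).
#' @param width_bias_correction See [width_px()].
#' @param border_margin Border-exclusion margin in px.
#' @param exclude_border Exclude border-touching cells from summaries.
#' @param seed Integer seed for any stochastic step.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(um_per_px = 0.65, tile_px = 1024L,
                            tile_overlap = 0.1,
                            iou_dedup_threshold = 0.8,
                            confidence_floor = 0.25,
                            length_mode = "pixel_count",
                            width_bias_correction = FALSE,
                            border_margin = 0L, exclude_border = TRUE,
                            seed = 1L) {
  if (tile_px < 256L) stop("tile_px must be >= 256")
  if (iou_dedup_threshold <= 0 || iou_dedup_threshold > 1)
    stop("iou_dedup_threshold must lie in (0, 1]")
  if (confidence_floor <= 0 || confidence_floor > 1)
    stop("confidence_floor must lie in (0, 1]")
  structure(list(um_per_px = um_per_px, tile_px = as.integer(tile_px),
                 tile_overlap = tile_overlap,
                 iou_dedup_threshold = iou_dedup_threshold,
                 confidence_floor = confidence_floor,
                 length_mode = length_mode,
                 width_bias_correction = width_bias_correction,
                 border_margin = as.integer(border_margin),
                 exclude_border = exclude_border,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a flat key=value config file
#'
#' INI-style lines `key = value` (comments with `#`). Values are converted
#' to numeric/logical where possible. Keys are validated against
#' [pipeline_config()] and [scene_spec()] arguments; an unknown key is an
#' error naming the key.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  known <- unique(c(names(formals(pipeline_config)),
                    names(formals(scene_spec))))
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% known) stop("unknown config key: ", key)
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    out[[key]] <- if (!anyNA(num)) num
      else if (toupper(val) %in% c("TRUE", "FALSE")) as.logical(val)
      else val
  }
  out
}

#' Merge per-tile detections into full-image instances
#'
#' Shifts tile-local instances to global coordinates, collapses duplicate
#' detections of the same cell seen in overlapping tiles (same class, mask
#' IoU at or above the threshold; the higher-confidence copy survives), and
#' resolves tile-edge truncation: an instance touching an interior tile edge
#' is only trusted if some duplicate copy is complete (does not touch an
#' interior edge); otherwise the survivor is flagged `fragmented`.
#'
#' @param tile_instances List (one element per tile window) of lists of
#'   [instance_mask()] objects with tile-local offsets.
#' @param windows Tile windows from [tile_image()] (rows parallel to
#'   `tile_instances`).
#' @param image_width,image_height Global image dimensions.
#' @param iou_dedup_threshold Duplicate IoU threshold (default 0.8).
#' @return List with `instances` (global-coordinate masks, each carrying a
#'   logical attribute `"fragmented"`) and `log` (counts: n_input,
#'   n_duplicates_removed, n_fragmented, n_kept).
#' @export
merge_tile_detections <- function(tile_instances, windows,
                                  image_width, image_height,
                                  iou_dedup_threshold = 0.8) {
  if (length(tile_instances) != nrow(windows))
    stop("tile_instances and windows differ in length")
  flat <- list(); complete <- logical()
  for (t in seq_along(tile_instances)) {
    w <- windows[t, ]
    for (m in tile_instances[[t]]) {
      bb <- mask_bbox(m)  # tile-local
      if (bb[2] >= w$rows || bb[4] >= w$cols ||
          m$offset[1] + nrow(m$grid) > w$rows + 1L ||
          m$offset[2] + ncol(m$grid) > w$cols + 1L)
        stop("inconsistent offsets: instance exceeds its tile window")
      # which tile edges are interior (not the global border)?
      touches_tile_edge <-
        c(bb[1] == 0L, bb[2] == w$rows - 1L, bb[3] == 0L, bb[4] == w$cols - 1L)
      interior_edge <-
        c(w$row0 > 0L, w$row0 + w$rows < image_height,
          w$col0 > 0L, w$col0 + w$cols < image_width)
      g <- m
      g$offset <- c(m$offset[1] + w$row0, m$offset[2] + w$col0)
      flat[[length(flat) + 1L]] <- g
      complete <- c(complete, !any(touches_tile_edge & interior_edge))
    }
  }
  n_input <- length(flat)
  ord <- if (n_input > 0L) rank_predictions(lapply(flat, function(m) {
    if (is.na(m$confidence)) m$confidence <- 1
    m
  })) else integer()
  kept <- list(); kept_complete <- logical(); removed <- 0L
  for (i in ord) {
    m <- flat[[i]]
    dup <- FALSE
    for (k in seq_along(kept)) {
      if (kept[[k]]$class_label != m$class_label) next
      if (mask_iou(kept[[k]], m) >= iou_dedup_threshold) {
        kept_complete[k] <- kept_complete[k] || complete[i]
        # keep the more complete copy's mask when the survivor is truncated
        if (!attr(kept[[k]], "copy_complete") && complete[i]) {
          conf <- kept[[k]]$confidence
          kept[[k]] <- m
          kept[[k]]$confidence <- conf
          attr(kept[[k]], "copy_complete") <- TRUE
        }
        dup <- TRUE
        removed <- removed + 1L
        break
      }
    }
    if (!dup) {
      attr(m, "copy_complete") <- complete[i]
      kept[[length(kept) + 1L]] <- m
      kept_complete <- c(kept_complete, complete[i])
    }
  }
  kept <- lapply(seq_along(kept), function(k) {
    m <- kept[[k]]
    attr(m, "copy_complete") <- NULL
    attr(m, "fragmented") <- !kept_complete[k]
    m
  })
  n_frag <- sum(!kept_complete)
  list(instances = kept,
       log = data.frame(n_input = n_input, n_duplicates_removed = removed,
                        n_fragmented = n_frag, n_kept = length(kept)))
}

#' Simulate a synthetic scene bundle (pipeline step)
#'
#' Builds a [scene_spec()] from a config list (or file), renders the scene
#' and exports the bundle to `out_dir`.
#'
#' @param out_dir Output directory.
#' @param config Named list or path of a key=value config; only
#'   [scene_spec()] keys are used.
#' @param seed Overrides the spec seed when given.
#' @param image_id Bundle base name.
#' @return The `synthetic_scene`, invisibly.
#' @export
cli_simulate <- function(out_dir, config = list(), seed = NULL,
                         image_id = "scene") {
  if (is.character(config)) config <- read_config(config)
  keys <- intersect(names(config), names(formals(scene_spec)))
  bad <- setdiff(names(config),
                 unique(c(names(formals(scene_spec)),
                          names(formals(pipeline_config)))))
  if (length(bad) > 0L) stop("unknown config key: ", paste(bad, collapse = ", "))
  spec <- do.call(scene_spec, config[keys])
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  scene <- render_scene(spec)
  export_scene(scene, out_dir, image_id)
  message(sprintf("simulated %d instances (%d fibers, %d vessels) -> %s",
                  length(scene$instances), spec$n_fibers, spec$n_vessels,
                  out_dir))
  invisible(scene)
}

#' Measure an instance-mask bundle (pipeline step)
#'
#' Reads per-instance masks for `image_id` from `input_dir`, measures every
#' instance with border exclusion on the global frame, and writes the
#' per-instance CSV and per-class summary CSV to `out_dir`.
#'
#' @param input_dir Directory with `{image_id}_{idx}_{class}.png` masks.
#' @param out_dir Output directory.
#' @param image_id Image identifier.
#' @param config A [pipeline_config()].
#' @return The records data frame, invisibly.
#' @export
cli_measure <- function(input_dir, out_dir, image_id = "scene",
                        config = pipeline_config()) {
  masks <- read_instance_masks(input_dir, image_id)
  if (length(masks) == 0L) stop("zero instances found in ", input_dir)
  dims <- attr(masks, "image_dim")
  records <- measure_collection(
    masks, cal = calibration(config$um_per_px),
    image_width = dims[2], image_height = dims[1],
    exclude_border = config$exclude_border,
    image_id = image_id, length_mode = config$length_mode,
    width_bias_correction = config$width_bias_correction,
    border_margin = config$border_margin)
  summaries <- do.call(rbind, lapply(split(records[!records$excluded, ],
                                           records$class[!records$excluded]),
                                     function(r)
    do.call(rbind, lapply(c("length_um", "width_um", "area_um2"),
                          function(f)
      summarize_records(r, f, group_id = r$class[1])))))
  export_report(records = records, summaries = summaries, dir = out_dir,
                prefix = image_id)
  message(sprintf("measured %d instances (%d excluded at border)",
                  nrow(records), sum(records$excluded)))
  invisible(records)
}

# pooled AP over several images: per-image greedy matching, prediction list
# pooled before ranking (COCO convention)
pooled_ap <- function(preds_by_image, gts_by_image, iou_threshold, cls) {
  rows <- list(); ngt <- 0L
  for (id in names(gts_by_image)) {
    gc <- Filter(function(g) g$class_label == cls, gts_by_image[[id]])
    pc <- Filter(function(p) p$class_label == cls,
                 if (id %in% names(preds_by_image)) preds_by_image[[id]]
                 else list())
    ngt <- ngt + length(gc)
    if (length(pc) == 0L) next
    if (length(gc) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        confidence = vapply(pc, `[[`, 0, "confidence"),
        instance_id = vapply(pc, `[[`, "", "instance_id"),
        tp = FALSE, stringsAsFactors = FALSE)
      next
    }
    m <- match_instances(pc, gc, iou_threshold, class_aware = TRUE)
    rows[[length(rows) + 1L]] <-
      m$pred[, c("confidence", "instance_id", "tp")]
  }
  if (ngt == 0L) return(NA_real_)
  if (length(rows) == 0L) return(0)
  df <- do.call(rbind, rows)
  df <- df[order(-df$confidence, df$instance_id), ]
  cum_tp <- cumsum(df$tp); cum_fp <- cumsum(!df$tp)
  recall <- cum_tp / ngt
  precision <- cum_tp / (cum_tp + cum_fp)
  grid <- seq(0, 1, by = 0.01)
  mean(vapply(grid, function(r) {
    ok <- recall >= r - 1e-12
    if (any(ok)) max(precision[ok]) else 0
  }, 0))
}

#' Evaluate predictions against ground truth over a set of images
#'
#' Per-image greedy matching with pooled TP/FP/FN for precision, recall and
#' F1 at IoU 0.5, and pooled-prediction-list AP per class at IoU 0.5 to 0.95
#' (step 0.05). Writes the metrics JSON and the PR / F1-confidence curve
#' CSVs when `out_dir` is given.
#'
#' @param preds_by_image Named list (image id -> list of prediction
#'   [instance_mask()]s with confidences).
#' @param gts_by_image Named list (image id -> list of ground-truth masks).
#' @param out_dir Optional output directory.
#' @param config A [pipeline_config()] (confidence floor applied to
#'   predictions).
#' @return List: map50, map50_95, per-class AP table, precision, recall, f1,
#'   counts, f1_curve.
#' @export
cli_evaluate <- function(preds_by_image, gts_by_image, out_dir = NULL,
                         config = pipeline_config()) {
  missing_ids <- setdiff(names(preds_by_image), names(gts_by_image))
  if (length(missing_ids) > 0L)
    stop("prediction image ids without ground truth: ",
         paste(missing_ids, collapse = ", "))
  preds_by_image <- lapply(preds_by_image, function(ps)
    Filter(function(p) is.na(p$confidence) ||
             p$confidence >= config$confidence_floor, ps))
  n_pred <- sum(lengths(preds_by_image))
  if (n_pred == 0L)
    warning("no predictions above the confidence floor")
  classes <- sort(unique(unlist(lapply(gts_by_image, function(gs)
    vapply(gs, `[[`, "", "class_label")))))
  thresholds <- seq(0.5, 0.95, by = 0.05)
  ap_rows <- list()
  for (cls in classes) for (thr in thresholds) {
    ap <- pooled_ap(preds_by_image, gts_by_image, thr, cls)
    ap_rows[[length(ap_rows) + 1L]] <-
      data.frame(class = cls, iou_threshold = thr, ap = ap,
                 stringsAsFactors = FALSE)
  }
  ap_df <- do.call(rbind, ap_rows)
  ap_df <- ap_df[!is.na(ap_df$ap), ]
  map50 <- mean(ap_df$ap[abs(ap_df$iou_threshold - 0.5) < 1e-9])
  map50_95 <- mean(ap_df$ap)
  tp <- fp <- fn <- 0L
  f1_acc <- NULL
  for (id in names(gts_by_image)) {
    pc <- if (id %in% names(preds_by_image)) preds_by_image[[id]] else list()
    gc <- gts_by_image[[id]]
    if (length(gc) == 0L && length(pc) == 0L) next
    if (length(gc) == 0L) { fp <- fp + length(pc); next }
    m <- match_instances(pc, gc, 0.5, class_aware = TRUE)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
  }
  prf <- precision_recall_f1(tp, fp, fn)
  all_preds <- unlist(preds_by_image, recursive = FALSE)
  # pooled f1-confidence curve: counts summed over images per cutoff
  grid <- seq(0, 1, by = 0.01)
  f1c <- vapply(grid, function(cutoff) {
    tp2 <- fp2 <- fn2 <- 0L
    for (id in names(gts_by_image)) {
      pc <- if (id %in% names(preds_by_image)) preds_by_image[[id]] else list()
      pc <- Filter(function(p) !is.na(p$confidence) &&
                     p$confidence >= cutoff, pc)
      gc <- gts_by_image[[id]]
      if (length(gc) == 0L) { fp2 <- fp2 + length(pc); next }
      m <- match_instances(pc, gc, 0.5, class_aware = TRUE)
      tp2 <- tp2 + m$tp; fp2 <- fp2 + m$fp; fn2 <- fn2 + m$fn
    }
    if (tp2 + fp2 + fn2 == 0L) return(1)
    unname(precision_recall_f1(tp2, fp2, fn2)["f1"])
  }, 0)
  f1_curve <- data.frame(confidence = grid, f1 = f1c)
  out <- list(map50 = map50, map50_95 = map50_95, ap = ap_df,
              precision = unname(prf["precision"]),
              recall = unname(prf["recall"]), f1 = unname(prf["f1"]),
              tp = tp, fp = fp, fn = fn, f1_curve = f1_curve)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(map50 = map50, map50_95 = map50_95,
           precision = out$precision, recall = out$recall, f1 = out$f1,
           tp = tp, fp = fp, fn = fn,
           ap = ap_df), file.path(out_dir, "metrics.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    utils::write.csv(f1_curve, file.path(out_dir, "f1_confidence.csv"),
                     row.names = FALSE)
  }
  out
}

#' Compare two measurement CSVs (pipeline step)
#'
#' Reads two per-instance CSVs in the measurement schema, compares `field`
#' between them (group 1 is the reference) and writes the comparison JSON.
#'
#' @param csv_1,csv_2 Paths to measurement CSVs.
#' @param field Column to compare (default `"length_um"`).
#' @param out_dir Optional output directory for the JSON.
#' @param group_ids Labels for the two groups.
#' @return The `comparison_result`, invisibly.
#' @export
cli_compare <- function(csv_1, csv_2, field = "length_um", out_dir = NULL,
                        group_ids = c("group1", "group2")) {
  r1 <- utils::read.csv(csv_1, stringsAsFactors = FALSE)
  r2 <- utils::read.csv(csv_2, stringsAsFactors = FALSE)
  for (nm in c(field, "class")) {
    if (!nm %in% names(r1)) stop("column '", nm, "' missing from ", csv_1)
    if (!nm %in% names(r2)) stop("column '", nm, "' missing from ", csv_2)
  }
  cmp <- compare_groups(r1, r2, field = field, group_ids = group_ids)
  if (!is.null(out_dir))
    export_report(comparisons = list(cmp), dir = out_dir,
                  prefix = paste(group_ids, collapse = "_vs_"))
  message(sprintf("%s: %+.2f%% change, t = %.4f, p = %.4g", field,
                  cmp$percent_change, cmp$t_statistic, cmp$p_value))
  invisible(cmp)
}

#' Convert between VGG JSON and YOLO segmentation labels
#'
#' @param input Path to a VGG JSON (direction `"vgg2yolo"`) or a YOLO label
#'   txt (direction `"yolo2vgg"`).
#' @param out Output directory (vgg2yolo: one `.txt` per image) or JSON path
#'   (yolo2vgg).
#' @param direction `"vgg2yolo"` or `"yolo2vgg"`.
#' @param class_order Class-index order.
#' @param image_id,width_px,height_px Required for `"yolo2vgg"`.
#' @return Invisibly, the written paths.
#' @export
cli_convert <- function(input, out, direction = c("vgg2yolo", "yolo2vgg"),
                        class_order = c("fiber", "vessel"),
                        image_id = NULL, width_px = NULL, height_px = NULL) {
  direction <- match.arg(direction)
  if (direction == "vgg2yolo") {
    sets <- read_vgg_json(input)
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(sets, function(s) {
      p <- file.path(out, paste0(tools::file_path_sans_ext(s$image_id),
                                 ".txt"))
      write_yolo_seg_labels(s, class_order, path = p)
      p
    }, "")
    invisible(paths)
  } else {
    if (is.null(image_id) || is.null(width_px) || is.null(height_px))
      stop("yolo2vgg needs image_id, width_px and height_px")
    set <- read_yolo_seg_labels(input, image_id, width_px, height_px,
                                class_order)
    write_vgg_json(set, out)
    invisible(out)
  }
}
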