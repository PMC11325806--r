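#' Read VGG Image Annotator polygon annotations
#'
#' Accepts both the VIA project export (a top-level `_via_img_metadata` map)
#' and the plain image-keyed dialect where each top-level entry holds
#' `filename` and `regions`. Only polygon regions (with
#' `shape_attributes$all_points_x` / `all_points_y`) are read. The class label
#' is taken from the first region attribute whose value is `"fiber"` or
#' `"vessel"` (case-insensitive); failing that, from an attribute named
#' `label` or `class`. Unknown labels are preserved verbatim with a warning.
#' Polygons with fewer than 3 points are dropped and the count reported.
#' Regions missing shape attributes are collected as per-region errors
#' (attached as attribute `"errors"`) without aborting the read.
#'
#' Image dimensions are taken from `file_attributes$width`/`height` when
#' present (our own writer stores them); otherwise they are inferred from the
#' polygon extent.
#'
#' @param path Path to the JSON file.
#' @return A list of [annotation_set()] objects, one per image entry.
#' @export
read_vgg_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed VGG JSON in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  entries <- if (!is.null(doc[["_via_img_metadata"]]))
    doc[["_via_img_metadata"]] else doc
  # keep only entries that look like VIA image records
  keep <- vapply(entries, function(e)
    is.list(e) && (!is.null(e$regions) || !is.null(e$filename)), TRUE)
  entries <- entries[keep]
  if (length(entries) == 0L)
    stop("malformed VGG JSON in '", path,
         "': no image entries with 'regions'/'filename' keys")

  dropped_short <- 0L
  errors <- character()
  unknown <- character()
  sets <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    image_id <- if (!is.null(e$filename)) as.character(e$filename)
                else names(entries)[i]
    fa <- e$file_attributes
    anns <- list()
    regions <- e$regions
    if (is.null(regions)) regions <- list()
    for (k in seq_along(regions)) {
      reg <- regions[[k]]
      sa <- reg$shape_attributes
      if (is.null(sa) || is.null(sa$all_points_x) || is.null(sa$all_points_y)) {
        errors <- c(errors, sprintf(
          "%s region %d: missing polygon shape_attributes", image_id, k))
        next
      }
      xs <- as.numeric(unlist(sa$all_points_x))
      ys <- as.numeric(unlist(sa$all_points_y))
      if (length(xs) != length(ys)) {
        errors <- c(errors, sprintf(
          "%s region %d: all_points_x/all_points_y length mismatch",
          image_id, k))
        next
      }
      if (length(xs) < 3L) { dropped_short <- dropped_short + 1L; next }
      lab <- vgg_region_label(reg$region_attributes)
      if (!(tolower(lab) %in% c("fiber", "vessel"))) unknown <- c(unknown, lab)
      anns[[length(anns) + 1L]] <-
        polygon_annotation(lab, cbind(xs, ys))
    }
    wh <- vgg_entry_dims(fa, anns)
    sets[[i]] <- annotation_set(image_id, wh[1], wh[2], anns)
  }
  if (dropped_short > 0L)
    warning(dropped_short, " polygon(s) with < 3 points dropped")
  if (length(unknown) > 0L)
    warning("unknown class label(s) preserved verbatim: ",
            paste(unique(unknown), collapse = ", "))
  if (length(errors) > 0L) {
    warning(length(errors), " region(s) skipped with errors")
    attr(sets, "errors") <- errors
  }
  sets
}

vgg_region_label <- function(ra) {
  if (is.null(ra) || length(ra) == 0L) return("unlabeled")
  vals <- vapply(ra, function(v) as.character(v)[1], "")
  hit <- which(tolower(vals) %in% c("fiber", "vessel"))
  if (length(hit) > 0L) return(vals[hit[1]])
  named <- which(tolower(names(ra)) %in% c("label", "class"))
  if (length(named) > 0L) return(vals[named[1]])
  vals[1]
}

vgg_entry_dims <- function(fa, anns) {
  if (!is.null(fa$width) && !is.null(fa$height))
    return(c(as.integer(fa$width), as.integer(fa$height)))
  if (length(anns) == 0L) return(c(1L, 1L))
  allv <- do.call(rbind, lapply(anns, `[[`, "vertices"))
  c(as.integer(ceiling(max(allv[, 1])) + 1L),
    as.integer(ceiling(max(allv[, 2])) + 1L))
}

#' Write annotation sets as a VGG Image Annotator project JSON
#'
#' Writes the `_via_img_metadata` project dialect with image dimensions
#' stored in `file_attributes`, so [read_vgg_json()] round-trips exactly.
#'
#' @param sets A list of [annotation_set()] objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vgg_json <- function(sets, path) {
  if (inherits(sets, "annotation_set")) sets <- list(sets)
  meta <- list()
  for (s in sets) {
    regions <- lapply(s$annotations, function(a) {
      list(shape_attributes = list(
             name = "polygon",
             all_points_x = as.numeric(a$vertices[, 1]),
             all_points_y = as.numeric(a$vertices[, 2])),
           region_attributes = list(label = a$class_label))
    })
    meta[[paste0(s$image_id, "-1")]] <- list(
      filename = s$image_id,
      size = -1L,
      regions = regions,
      file_attributes = list(width = s$width_px, height = s$height_px))
  }
  jsonlite::write_json(list(`_via_img_metadata` = meta), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
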