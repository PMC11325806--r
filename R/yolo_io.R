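#' Write YOLO segmentation label lines for one image
#'
#' One line per annotation: the 0-based class index followed by the polygon
#' vertices normalized to \[0, 1\] by image width/height, fixed 6-decimal
#' format. Round-trips with [read_yolo_seg_labels()] to within 1e-5 of an
#' image dimension.
#'
#' @param set An [annotation_set()].
#' @param class_order Character vector giving the class-index order, e.g.
#'   `c("fiber", "vessel")`.
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of label lines (invisibly when `path` is given).
#' @export
write_yolo_seg_labels <- function(set, class_order = c("fiber", "vessel"),
                                  path = NULL) {
  lines <- vapply(set$annotations, function(a) {
    idx <- match(a$class_label, class_order)
    if (is.na(idx))
      stop("class label '", a$class_label, "' not in class_order")
    xn <- a$vertices[, 1] / set$width_px
    yn <- a$vertices[, 2] / set$height_px
    paste(idx - 1L,
          paste(sprintf("%.6f %.6f", xn, yn), collapse = " "))
  }, "")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read YOLO segmentation label lines
#'
#' Inverse of [write_yolo_seg_labels()]. An optional trailing confidence
#' column (odd number of coordinates plus one) is honoured when
#' `confidence_column = TRUE`.
#'
#' @param x Path to a `.txt` label file, or a character vector of lines.
#' @param image_id Identifier for the resulting set.
#' @param width_px,height_px Image dimensions used to de-normalize.
#' @param class_order Class-index order used at write time.
#' @param confidence_column If `TRUE`, the last number of each line is read
#'   as a confidence score.
#' @return An [annotation_set()].
#' @export
read_yolo_seg_labels <- function(x, image_id, width_px, height_px,
                                 class_order = c("fiber", "vessel"),
                                 confidence_column = FALSE) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(trimws(lines))]
  anns <- lapply(lines, function(ln) {
    num <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    idx <- as.integer(num[1])
    if (idx < 0L || idx >= length(class_order))
      stop("class index ", idx, " out of range for class_order")
    rest <- num[-1]
    conf <- NA_real_
    if (confidence_column) {
      conf <- rest[length(rest)]
      rest <- rest[-length(rest)]
    }
    if (length(rest) %% 2L != 0L || length(rest) < 6L)
      stop("malformed YOLO segmentation line: ", ln)
    v <- matrix(rest, ncol = 2, byrow = TRUE)
    v[, 1] <- v[, 1] * width_px
    v[, 2] <- v[, 2] * height_px
    polygon_annotation(class_order[idx + 1L], v, confidence = conf)
  })
  annotation_set(image_id, width_px, height_px, anns)
}
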