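#' Mask intersection-over-union
#'
#' |A intersect B| / |A union B| over foreground pixels of two instance masks
#' placed in one image frame via their offsets. Disjoint masks give 0.
#'
#' @param a,b [instance_mask()] objects.
#' @return IoU in \[0, 1\].
#' @export
mask_iou <- function(a, b) {
  na <- sum(a$grid); nb <- sum(b$grid)
  if (na == 0L && nb == 0L) stop("IoU undefined: both masks empty")
  ar <- a$offset[1] + c(0L, nrow(a$grid) - 1L)
  ac <- a$offset[2] + c(0L, ncol(a$grid) - 1L)
  br <- b$offset[1] + c(0L, nrow(b$grid) - 1L)
  bc <- b$offset[2] + c(0L, ncol(b$grid) - 1L)
  r0 <- max(ar[1], br[1]); r1 <- min(ar[2], br[2])
  c0 <- max(ac[1], bc[1]); c1 <- min(ac[2], bc[2])
  inter <- 0L
  if (r0 <= r1 && c0 <= c1) {
    sa <- a$grid[(r0 - ar[1] + 1L):(r1 - ar[1] + 1L),
                 (c0 - ac[1] + 1L):(c1 - ac[1] + 1L), drop = FALSE]
    sb <- b$grid[(r0 - br[1] + 1L):(r1 - br[1] + 1L),
                 (c0 - bc[1] + 1L):(c1 - bc[1] + 1L), drop = FALSE]
    inter <- sum(sa * sb)
  }
  inter / (na + nb - inter)
}

# deterministic prediction ranking: confidence descending, ties by
# lexicographic instance id
rank_predictions <- function(preds) {
  conf <- vapply(preds, `[[`, 0, "confidence")
  ids <- vapply(preds, `[[`, "", "instance_id")
  order(-conf, ids)
}

#' Greedy confidence-ordered matching of predictions to ground truth
#'
#' Predictions are processed in descending confidence (ties broken by
#' instance id); each is matched to the not-yet-matched ground-truth
#' instance of the same class (when `class_aware`) with the highest IoU at
#' or above the threshold. Unmatched predictions are false positives,
#' unmatched ground truths false negatives. Ground truths that overlap each
#' other are each independently matchable: translucent-overlap scenes never
#' lose a ground truth to its neighbour. True negatives are undefined for
#' instance detection and not reported.
#'
#' @param preds List of [instance_mask()] predictions with confidences.
#' @param gts List of ground-truth [instance_mask()] objects.
#' @param iou_threshold Match threshold in (0, 1].
#' @param class_aware Require class agreement for a match (default TRUE).
#' @return List with `pred` (data frame: instance_id, class, confidence,
#'   matched_gt, iou, tp), `gt` (data frame: instance_id, class, matched),
#'   and counts `tp`, `fp`, `fn`, plus `iou_threshold`.
#' @export
match_instances <- function(preds, gts, iou_threshold = 0.5,
                            class_aware = TRUE) {
  if (iou_threshold <= 0 || iou_threshold > 1)
    stop("iou_threshold must lie in (0, 1]")
  npred <- length(preds); ngt <- length(gts)
  gt_class <- vapply(gts, `[[`, "", "class_label")
  gt_id <- vapply(gts, `[[`, "", "instance_id")
  gt_taken <- rep(FALSE, ngt)
  ord <- rank_predictions(preds)
  rows <- vector("list", npred)
  for (k in seq_along(ord)) {
    i <- ord[k]
    p <- preds[[i]]
    best_iou <- -1; best_j <- NA_integer_
    for (j in seq_len(ngt)) {
      if (gt_taken[j]) next
      if (class_aware && gt_class[j] != p$class_label) next
      iou <- mask_iou(p, gts[[j]])
      if (iou >= iou_threshold && iou > best_iou) {
        best_iou <- iou; best_j <- j
      }
    }
    tp <- !is.na(best_j)
    if (tp) gt_taken[best_j] <- TRUE
    rows[[i]] <- data.frame(
      instance_id = p$instance_id, class = p$class_label,
      confidence = p$confidence,
      matched_gt = if (tp) gt_id[best_j] else NA_character_,
      iou = if (tp) best_iou else NA_real_,
      tp = tp, rank = k, stringsAsFactors = FALSE)
  }
  pred_df <- if (npred > 0L) do.call(rbind, rows) else
    data.frame(instance_id = character(), class = character(),
               confidence = numeric(), matched_gt = character(),
               iou = numeric(), tp = logical(), rank = integer(),
               stringsAsFactors = FALSE)
  gt_df <- data.frame(instance_id = gt_id, class = gt_class,
                      matched = gt_taken, stringsAsFactors = FALSE)
  list(pred = pred_df, gt = gt_df,
       tp = sum(gt_taken), fp = npred - sum(gt_taken),
       fn = ngt - sum(gt_taken), iou_threshold = iou_threshold)
}

#' Precision, recall and F1 from match counts
#'
#' P = tp / (tp + fp) (defined as 1 when no predictions were made),
#' R = tp / (tp + fn) (1 when there is nothing to find),
#' F1 = 2PR / (P + R) (0 when P + R = 0).
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named numeric vector c(precision, recall, f1).
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  if (tp < 0 || fp < 0 || fn < 0) stop("counts must be non-negative")
  if (tp + fp + fn == 0) stop("no instances: metrics undefined")
  p <- if (tp + fp == 0) 1 else tp / (tp + fp)
  r <- if (tp + fn == 0) 1 else tp / (tp + fn)
  c(precision = p, recall = r, f1 = f1_score(p, r))
}

#' F1 score from precision and recall
#'
#' The harmonic mean 2PR / (P + R), 0 when both are 0.
#'
#' @param precision,recall Values in \[0, 1\].
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Average precision at one IoU threshold
#'
#' Predictions are ranked by confidence (ties by id), matched greedily, and
#' the cumulative precision/recall points are summarized by COCO-style
#' 101-point interpolation: AP is the mean over recalls r in {0, 0.01, ...,
#' 1} of the maximum precision at recall >= r (0 where unreached). A
#' continuous (VOC-style) integration of the precision envelope is available
#' with `interpolation = "continuous"`.
#'
#' @param preds,gts As in [match_instances()].
#' @param iou_threshold Match threshold.
#' @param class_aware Require class agreement.
#' @param interpolation `"coco101"` (default) or `"continuous"`.
#' @return List with `ap` and `pr_points` (data frame recall/precision in
#'   rank order).
#' @export
average_precision <- function(preds, gts, iou_threshold = 0.5,
                              class_aware = TRUE,
                              interpolation = c("coco101", "continuous")) {
  interpolation <- match.arg(interpolation)
  if (length(gts) == 0L) stop("undefined AP: no ground-truth instances")
  ngt <- length(gts)
  if (length(preds) == 0L)
    return(list(ap = 0,
                pr_points = data.frame(recall = 0, precision = 1)))
  m <- match_instances(preds, gts, iou_threshold, class_aware)
  tp_flags <- m$pred$tp[order(m$pred$rank)]
  cum_tp <- cumsum(tp_flags)
  cum_fp <- cumsum(!tp_flags)
  recall <- cum_tp / ngt
  precision <- cum_tp / (cum_tp + cum_fp)
  pr <- data.frame(recall = recall, precision = precision)
  ap <- if (interpolation == "coco101") {
    grid <- seq(0, 1, by = 0.01)
    mean(vapply(grid, function(r) {
      ok <- recall >= r - 1e-12
      if (any(ok)) max(precision[ok]) else 0
    }, 0))
  } else {
    # area under the precision envelope over recall
    env_r <- c(0, recall)
    env_p <- vapply(recall, function(r) max(precision[recall >= r - 1e-12]), 0)
    sum(diff(env_r) * env_p)
  }
  list(ap = ap, pr_points = pr)
}

#' Per-class AP across IoU thresholds, mAP@0.5 and mAP@0.5:0.95
#'
#' AP is computed per ground-truth class at IoU thresholds 0.50 to 0.95 in
#' steps of 0.05. `map50` averages the per-class AP at 0.50; `map50_95`
#' averages over classes and thresholds. Classes absent from the ground
#' truth are excluded. Also returns the pooled PR points and F1-confidence
#' curve at IoU 0.5.
#'
#' @param preds,gts As in [match_instances()].
#' @param interpolation Passed to [average_precision()].
#' @return Object of class `ap_summary`: list with `ap` (data frame class x
#'   iou_threshold x ap), `map50`, `map50_95`, `pr_points`, `f1_curve`,
#'   `best_confidence`, `best_f1`.
#' @export
map_metrics <- function(preds, gts, interpolation = "coco101") {
  if (length(gts) == 0L) stop("no ground-truth instances")
  thresholds <- seq(0.5, 0.95, by = 0.05)
  classes <- sort(unique(vapply(gts, `[[`, "", "class_label")))
  rows <- list()
  for (cls in classes) {
    gc <- Filter(function(g) g$class_label == cls, gts)
    pc <- Filter(function(p) p$class_label == cls, preds)
    for (thr in thresholds) {
      ap <- average_precision(pc, gc, thr, class_aware = TRUE,
                              interpolation = interpolation)$ap
      rows[[length(rows) + 1L]] <-
        data.frame(class = cls, iou_threshold = thr, ap = ap,
                   stringsAsFactors = FALSE)
    }
  }
  ap_df <- do.call(rbind, rows)
  map50 <- mean(ap_df$ap[abs(ap_df$iou_threshold - 0.5) < 1e-9])
  map50_95 <- mean(ap_df$ap)
  pr <- average_precision(preds, gts, 0.5, class_aware = TRUE,
                          interpolation = interpolation)$pr_points
  f1c <- f1_confidence_curve(preds, gts, 0.5)
  structure(list(ap = ap_df, map50 = map50, map50_95 = map50_95,
                 pr_points = pr, f1_curve = f1c,
                 best_confidence = attr(f1c, "best_confidence"),
                 best_f1 = attr(f1c, "best_f1")),
            class = "ap_summary")
}

#' @export
print.ap_summary <- function(x, ...) {
  cat(sprintf("<ap_summary: mAP@0.5 = %.3f, mAP@0.5:0.95 = %.3f, best F1 = %.3f at conf %.2f>\n",
              x$map50, x$map50_95, x$best_f1, x$best_confidence))
  invisible(x)
}

#' F1 versus confidence-cutoff curve
#'
#' For each confidence cutoff c on a grid, predictions with confidence >= c
#' are matched (class-aware, pooled over classes) and the pooled F1 is
#' recorded. The attribute `best_confidence` holds the cutoff maximizing F1
#' (first on ties).
#'
#' @param preds,gts As in [match_instances()].
#' @param iou_threshold Match threshold.
#' @param grid Confidence cutoffs (default 101 points on \[0, 1\]).
#' @return Data frame (confidence, f1) with attributes `best_confidence`,
#'   `best_f1`.
#' @export
f1_confidence_curve <- function(preds, gts, iou_threshold = 0.5,
                                grid = seq(0, 1, by = 0.01)) {
  f1s <- vapply(grid, function(cutoff) {
    keep <- Filter(function(p) p$confidence >= cutoff, preds)
    if (length(keep) == 0L && length(gts) == 0L) return(1)
    if (length(keep) == 0L) return(0)
    m <- match_instances(keep, gts, iou_threshold, class_aware = TRUE)
    unname(precision_recall_f1(m$tp, m$fp, m$fn)["f1"])
  }, 0)
  out <- data.frame(confidence = grid, f1 = f1s)
  best <- which.max(f1s)
  attr(out, "best_confidence") <- grid[best]
  attr(out, "best_f1") <- f1s[best]
  out
}
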