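#' Summary statistics of one measured field for a group
#'
#' Moments and quartiles over non-excluded records. Quartiles use linear
#' interpolation between order statistics (the common plotting default,
#' `stats::quantile` type 7).
#'
#' @param records Measurement data frame from [measure_collection()].
#' @param field Column to summarize (e.g. `"length_um"`).
#' @param group_id Label recorded in the output.
#' @return One-row data frame: group_id, field, n, mean, sd, median, q1, q3,
#'   min, max.
#' @export
summarize_records <- function(records, field = "length_um",
                              group_id = "group") {
  if (!field %in% names(records))
    stop("field '", field, "' not in records")
  keep <- if ("excluded" %in% names(records)) !records$excluded
          else rep(TRUE, nrow(records))
  x <- records[[field]][keep]
  if (length(x) == 0L) stop("no records left after exclusion")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(group_id = group_id, field = field, n = length(x),
             mean = mean(x), sd = stats::sd(x), median = q[2],
             q1 = q[1], q3 = q[3], min = min(x), max = max(x),
             stringsAsFactors = FALSE)
}

#' Two-sample t-test on raw values
#'
#' The two-independent-samples t statistic t = (mean1 - mean2) / SED, where
#' SED is the standard error of the difference between the means. The
#' default pools the variances (Student); `equal_var = FALSE` uses the Welch
#' form with Welch-Satterthwaite degrees of freedom (recommended for
#' unequal group sizes). Two-sided p-value by default.
#'
#' @param sample_1,sample_2 Numeric vectors, each with >= 2 values.
#' @param equal_var Pool the variances (default TRUE).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List of class `comparison_result`: t_statistic, p_value, df,
#'   mean_1, mean_2, percent_change (of mean_2 relative to mean_1),
#'   equal_var.
#' @export
t_test_groups <- function(sample_1, sample_2, equal_var = TRUE,
                          alternative = "two.sided") {
  if (length(sample_1) < 2L || length(sample_2) < 2L)
    stop("each sample needs at least 2 values")
  if (stats::sd(sample_1) == 0 && stats::sd(sample_2) == 0)
    stop("degenerate samples: zero variance in both groups")
  ht <- tryCatch(
    stats::t.test(sample_1, sample_2, var.equal = equal_var,
                  alternative = alternative),
    error = function(e) stop("degenerate samples: ", conditionMessage(e),
                             call. = FALSE))
  structure(list(t_statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 df = unname(ht$parameter),
                 mean_1 = mean(sample_1), mean_2 = mean(sample_2),
                 percent_change = percent_change(mean(sample_1),
                                                 mean(sample_2)),
                 equal_var = equal_var),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison: means %.2f vs %.2f (%+.2f%%), t = %.4f, df = %.1f, p = %.4g>\n",
    x$mean_1, x$mean_2, x$percent_change, x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' Percent change of a test mean relative to a reference mean
#'
#' 100 * (mean_test - mean_ref) / mean_ref.
#'
#' @param mean_ref Reference (e.g. wildtype) mean, non-zero.
#' @param mean_test Test (e.g. transgenic) mean.
#' @return Signed percent change.
#' @export
percent_change <- function(mean_ref, mean_test) {
  if (mean_ref == 0) stop("zero reference mean: percent change undefined")
  100 * (mean_test - mean_ref) / mean_ref
}

#' Compare a measured field between two groups of records
#'
#' Runs the two-sample t-test on the field values of non-excluded records
#' and reports the percent change of group 2 relative to group 1 together
#' with both group summaries.
#'
#' @param records_1,records_2 Measurement data frames (reference first).
#' @param field Column to compare.
#' @param equal_var Passed to [t_test_groups()].
#' @param group_ids Length-2 labels for the two groups.
#' @return A `comparison_result` with an extra `summaries` element (two-row
#'   data frame) and `field`.
#' @export
compare_groups <- function(records_1, records_2, field = "length_um",
                           equal_var = TRUE,
                           group_ids = c("group1", "group2")) {
  s1 <- summarize_records(records_1, field, group_ids[1])
  s2 <- summarize_records(records_2, field, group_ids[2])
  keep1 <- if ("excluded" %in% names(records_1)) !records_1$excluded
           else TRUE
  keep2 <- if ("excluded" %in% names(records_2)) !records_2$excluded
           else TRUE
  res <- t_test_groups(records_1[[field]][keep1],
                       records_2[[field]][keep2], equal_var = equal_var)
  res$summaries <- rbind(s1, s2)
  res$field <- field
  res
}

#' Export measurement and comparison reports
#'
#' Writes a per-instance CSV (micrometer fields rounded to 2 decimals), a
#' per-group summary CSV and, when comparisons are given, a comparison JSON
#' (statistics at 4 decimals).
#'
#' @param records Per-instance measurement data frame (or NULL to skip).
#' @param summaries Data frame of group summaries (rbind of
#'   [summarize_records()] rows), or NULL.
#' @param comparisons List of `comparison_result` objects (possibly empty).
#' @param dir Output directory.
#' @param prefix File-name prefix (default "report").
#' @return Named list of written paths, invisibly.
#' @export
export_report <- function(records = NULL, summaries = NULL,
                          comparisons = list(), dir = ".",
                          prefix = "report") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  if (!is.null(records)) {
    rec <- records
    for (col in c("length_um", "width_um", "area_um2"))
      if (col %in% names(rec)) rec[[col]] <- round(rec[[col]], 2)
    paths$records <- file.path(dir, paste0(prefix, "_instances.csv"))
    utils::write.csv(rec, paths$records, row.names = FALSE)
  }
  if (!is.null(summaries)) {
    sm <- summaries
    num <- vapply(sm, is.numeric, TRUE)
    sm[num] <- lapply(sm[num], round, 4)
    paths$summaries <- file.path(dir, paste0(prefix, "_summary.csv"))
    utils::write.csv(sm, paths$summaries, row.names = FALSE)
  }
  if (length(comparisons) > 0L) {
    cj <- lapply(comparisons, function(cmp) {
      list(field = cmp$field,
           t_statistic = round(cmp$t_statistic, 4),
           p_value = signif(cmp$p_value, 4),
           df = round(cmp$df, 4),
           mean_1 = round(cmp$mean_1, 4), mean_2 = round(cmp$mean_2, 4),
           percent_change = round(cmp$percent_change, 4),
           equal_var = cmp$equal_var)
    })
    paths$comparisons <- file.path(dir, paste0(prefix, "_comparisons.json"))
    jsonlite::write_json(cj, paths$comparisons, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(paths)
}
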