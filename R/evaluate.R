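# Volume-level segmentation agreement metrics, aggregation, and the paired
# t-test used for model comparisons. One confusion triple (TP, FP, FN) is
# computed per case over the full 3D grid; per-slice averaging is
# deliberately not used, matching one score per patient.

#' Voxel-wise confusion counts
#'
#' @param pred,gt binary masks on the same grid.
#' @return list of class `confusion_counts` with `tp`, `fp`, `fn` (TN is
#'   unused by the metrics and not stored).
#' @export
confusion_counts <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)))
    stopf("prediction and ground truth must share one grid")
  p <- pred > 0; g <- gt > 0
  structure(list(tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g)),
            class = "confusion_counts")
}

#' Dice, precision and recall from confusion counts
#'
#' `DSC = 2TP / (FP + 2TP + FN)`, `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`. Conventions: if ground truth and prediction
#' are both empty all three metrics are 1; a ratio whose denominator alone
#' is 0 is 0.
#'
#' @param c a [confusion_counts()] (or list with tp, fp, fn).
#' @return list of class `seg_metrics` with `dsc`, `precision`, `recall`.
#' @export
seg_metrics <- function(c) {
  if (c$tp < 0 || c$fp < 0 || c$fn < 0) stopf("counts must be non-negative")
  if (c$tp + c$fp + c$fn == 0)
    return(structure(list(dsc = 1, precision = 1, recall = 1),
                     class = "seg_metrics"))
  ratio <- function(num, den) if (den == 0) 0 else num / den
  structure(list(dsc = ratio(2 * c$tp, c$fp + 2 * c$tp + c$fn),
                 precision = ratio(c$tp, c$tp + c$fp),
                 recall = ratio(c$tp, c$tp + c$fn)),
            class = "seg_metrics")
}

#' Aggregate per-case metrics into a summary
#'
#' Mean with sample (n-1) standard deviation (0 for a single case), median,
#' and range, per metric.
#'
#' @param values data.frame with columns `dsc`, `precision`, `recall` (one
#'   row per case), or a list of [seg_metrics()].
#' @return list of class `metric_summary`: per metric a list with `mean`,
#'   `sd`, `median`, `min`, `max`; plus `n`.
#' @export
aggregate_metrics <- function(values) {
  if (!is.data.frame(values)) {
    if (length(values) == 0) stopf("no metric values to aggregate")
    values <- do.call(rbind, lapply(values, function(v)
      data.frame(dsc = v$dsc, precision = v$precision, recall = v$recall)))
  }
  if (nrow(values) == 0) stopf("no metric values to aggregate")
  one <- function(x) list(mean = mean(x),
                          sd = if (length(x) < 2) 0 else sd(x),
                          median = median(x), min = min(x), max = max(x))
  structure(list(dsc = one(values$dsc), precision = one(values$precision),
                 recall = one(values$recall), n = nrow(values)),
            class = "metric_summary")
}

#' Paired t-test on per-case values
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences, with a
#' two-sided p-value from the Student t distribution with n-1 degrees of
#' freedom. All-equal pairs are degenerate and reported as t = 0, p = 1 with
#' the `degenerate` flag set.
#'
#' @param a,b equal-length numeric vectors paired by case.
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stopf("paired vectors must have equal length")
  n <- length(a)
  if (n < 2) stopf("paired t-test needs n >= 2")
  d <- a - b
  s <- sd(d)
  if (s == 0) {
    if (mean(d) == 0)
      return(list(t = 0, p = 1, df = n - 1, degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1,
                degenerate = TRUE))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1), df = n - 1,
       degenerate = FALSE)
}

#' Render a comparison report
#'
#' One row per model with mean +/- sd, median and range per metric, plus a
#' p-value column for models that have a comparison baseline.
#'
#' @param summaries named list of [aggregate_metrics()] summaries.
#' @param tests optional named numeric vector of p-values (names must be a
#'   subset of the model names).
#' @return data.frame of class `seg_report`.
#' @export
make_report <- function(summaries, tests = NULL) {
  if (length(summaries) == 0) stopf("report needs at least one model")
  fmt <- function(s) c(sprintf("%.3f ± %.3f", s$mean, s$sd),
                       sprintf("%.3f", s$median),
                       sprintf("%.3f–%.3f", s$min, s$max))
  rows <- lapply(names(summaries), function(m) {
    s <- summaries[[m]]
    v <- c(fmt(s$dsc), fmt(s$precision), fmt(s$recall))
    data.frame(model = m,
               dsc_mean_sd = v[1], dsc_median = v[2], dsc_range = v[3],
               precision_mean_sd = v[4], precision_median = v[5],
               precision_range = v[6],
               recall_mean_sd = v[7], recall_median = v[8],
               recall_range = v[9],
               p_value = if (!is.null(tests) && m %in% names(tests))
                 sprintf("%.3g", tests[[m]]) else "",
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("seg_report", "data.frame"))
}

#' @export
print.seg_report <- function(x, ...) {
  cat(format_report_text(x))
  invisible(x)
}

#' Format a report as aligned text
#'
#' @param report a [make_report()] result.
#' @return single character string.
#' @export
format_report_text <- function(report) {
  cols <- names(report)
  w <- vapply(cols, function(cn) max(nchar(c(cn, report[[cn]]))), numeric(1))
  line <- function(vals) paste0(mapply(formatC, vals, width = w,
                                       MoreArgs = list(flag = "-")),
                                collapse = "  ")
  paste0(line(cols), "\n",
         paste(vapply(seq_len(nrow(report)), function(i)
           line(as.character(report[i, ])), character(1)), collapse = "\n"),
         "\n")
}

#' Write a report as CSV
#'
#' @param report a [make_report()] result.
#' @param path output path.
#' @export
write_report_csv <- function(report, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
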