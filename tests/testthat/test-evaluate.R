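# Brute-force voxel-loop oracle, deliberately independent of the vectorized
# implementation under test.
loop_confusion <- function(pred, gt) {
  tp <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] > 0 && gt[i] > 0) tp <- tp + 1L
    else if (pred[i] > 0) fp <- fp + 1L
    else if (gt[i] > 0) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, fn = fn)
}

test_that("confusion counts match an explicit voxel loop", {
  for (seed in 1:5) {
    pred <- random_mask(seed, c(8, 8, 8))
    gt <- random_mask(seed + 100, c(8, 8, 8))
    got <- confusion_counts(pred, gt)
    want <- loop_confusion(pred, gt)
    expect_identical(got$tp, want$tp)
    expect_identical(got$fp, want$fp)
    expect_identical(got$fn, want$fn)
  }
  m <- random_mask(1, c(8, 8, 8))
  cc <- confusion_counts(m, m)
  expect_equal(cc$fp, 0); expect_equal(cc$fn, 0); expect_equal(cc$tp, sum(m))
  empty <- m * 0
  cc2 <- confusion_counts(empty, m)
  expect_equal(cc2$tp, 0); expect_equal(cc2$fn, sum(m))
  expect_error(confusion_counts(m, array(0, c(4, 4, 4))), "grid")
})

test_that("metrics follow the confusion-count formulas and conventions", {
  sm <- seg_metrics(list(tp = 2, fp = 1, fn = 2))
  expect_equal(sm$dsc, 4 / 7)
  expect_equal(sm$precision, 2 / 3)
  expect_equal(sm$recall, 0.5)
  perfect <- seg_metrics(list(tp = 10, fp = 0, fn = 0))
  expect_equal(unlist(perfect[c("dsc", "precision", "recall")]),
               c(dsc = 1, precision = 1, recall = 1))
  miss <- seg_metrics(list(tp = 0, fp = 0, fn = 5))
  expect_equal(unlist(miss[c("dsc", "precision", "recall")]),
               c(dsc = 0, precision = 0, recall = 0))
  both_empty <- seg_metrics(list(tp = 0, fp = 0, fn = 0))
  expect_equal(both_empty$dsc, 1)
  expect_error(seg_metrics(list(tp = -1, fp = 0, fn = 0)), "non-negative")
})

test_that("dsc never decreases with an added true positive", {
  for (seed in 1:10) {
    cc <- dfnseg:::with_seed(seed, list(tp = sample(0:20, 1),
                                        fp = sample(0:20, 1),
                                        fn = sample(1:20, 1)))
    base <- seg_metrics(cc)$dsc
    up <- seg_metrics(list(tp = cc$tp + 1, fp = cc$fp, fn = cc$fn - 1))$dsc
    expect_gte(up, base)
    worse <- seg_metrics(list(tp = cc$tp, fp = cc$fp + 1, fn = cc$fn))
    if (cc$tp > 0) expect_lt(worse$precision, seg_metrics(cc)$precision)
  }
})

test_that("aggregation matches a sort-based recomputation", {
  vals <- data.frame(dsc = c(0.6, 0.8, 1.0), precision = c(0.5, 0.7, 0.9),
                     recall = c(0.4, 0.6, 0.8))
  s <- aggregate_metrics(vals)
  expect_equal(s$dsc$mean, 0.8)
  expect_equal(s$dsc$median, 0.8)
  expect_equal(s$dsc$min, 0.6); expect_equal(s$dsc$max, 1.0)
  # single case: sd 0 by convention
  s1 <- aggregate_metrics(data.frame(dsc = 0.7, precision = 0.7, recall = 0.7))
  expect_equal(s1$dsc$sd, 0)
  expect_equal(s1$n, 1)
  # 51 random values against an independent sort/mean oracle
  x <- dfnseg:::with_seed(12, runif(51))
  sx <- aggregate_metrics(data.frame(dsc = x, precision = x, recall = x))
  srt <- sort(x)
  expect_equal(sx$dsc$mean, sum(x) / 51)
  expect_equal(sx$dsc$median, srt[26])
  expect_equal(sx$dsc$min, srt[1]); expect_equal(sx$dsc$max, srt[51])
  expect_equal(sx$dsc$sd, sqrt(sum((x - mean(x))^2) / 50))
  expect_error(aggregate_metrics(data.frame()), "no metric")
})

test_that("paired t-test matches the incomplete-beta closed form", {
  # independent oracle: t CDF via the regularized incomplete beta function
  p_beta <- function(t, df) {
    x <- df / (df + t^2)
    p_one <- 0.5 * pbeta(x, df / 2, 0.5)
    2 * p_one
  }
  for (seed in 1:10) {
    a <- dfnseg:::with_seed(seed, runif(10))
    b <- dfnseg:::with_seed(seed + 99, runif(10))
    got <- paired_t_test(a, b)
    d <- a - b
    t_ref <- mean(d) / (sd(d) / sqrt(10))
    expect_equal(got$t, t_ref, tolerance = 1e-12)
    expect_equal(got$p, p_beta(abs(t_ref), 9), tolerance = 1e-9)
  }
  deg <- paired_t_test(1:5, 1:5)
  expect_equal(deg$t, 0); expect_equal(deg$p, 1)
  expect_true(deg$degenerate)
  sym <- paired_t_test(c(1, 0), c(0, 1))
  expect_equal(sym$t, 0); expect_equal(sym$p, 1)
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("reports carry the table structure and round trip through CSV", {
  td <- withr::local_tempdir()
  mk <- function(seed) aggregate_metrics(data.frame(
    dsc = dfnseg:::with_seed(seed, runif(5)),
    precision = dfnseg:::with_seed(seed + 1, runif(5)),
    recall = dfnseg:::with_seed(seed + 2, runif(5))))
  summaries <- list("DCNN-F" = mk(1), "DFN-F" = mk(4), "DFN-R" = mk(7))
  tests <- c("DFN-F" = 0.26, "DFN-R" = 0.69)
  rep <- make_report(summaries, tests)
  expect_equal(nrow(rep), 3)
  expect_true(all(c("dsc_mean_sd", "dsc_median", "dsc_range",
                    "p_value") %in% names(rep)))
  # p-value present only for models with a baseline
  expect_identical(rep$p_value[rep$model == "DCNN-F"], "")
  expect_false(rep$p_value[rep$model == "DFN-R"] == "")
  p <- file.path(td, "report.csv")
  write_report_csv(rep, p)
  back <- read.csv(p, colClasses = "character")
  expect_equal(back$dsc_mean_sd, rep$dsc_mean_sd)
  expect_equal(back$model, rep$model)
  txt <- format_report_text(rep)
  expect_match(txt, "DFN-R")
})
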