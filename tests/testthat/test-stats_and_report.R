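test_that("chi-square goodness of fit uses the uncorrected Pearson statistic", {
  res <- chisq_goodness_of_fit(c(26, 1))
  expect_equal(res$statistic, 2 * (12.5^2 / 13.5))
  expect_equal(round(res$statistic, 3), 23.148)
  expect_equal(res$df, 1)
  expect_lt(res$p, 1e-4)
  expect_equal(res$p_formatted, "< 0.0001")
  expect_equal(res$expected, c(13.5, 13.5))

  expect_equal(chisq_goodness_of_fit(c(7, 7))$statistic, 0)
  expect_equal(chisq_goodness_of_fit(c(20, 10))$statistic, 10 / 3,
               tolerance = 1e-6)
  expect_error(chisq_goodness_of_fit(c(-1, 5)), "non-negative")
  expect_error(chisq_goodness_of_fit(c(0, 0)), "positive")
})

test_that("paired t-test matches the closed form and flags degeneracy", {
  res <- paired_t(c(2, 3, 4, 5, 6), rep(1, 5))
  expect_equal(res$t, 3 / (sd(1:5) / sqrt(5)))
  expect_equal(round(res$t, 4), 4.2426)
  expect_equal(res$df, 4)
  expect_false(res$undefined)

  expect_true(paired_t(1:5, 1:5)$undefined)
  expect_error(paired_t(1:3, 1:4), "equal length")
  expect_error(paired_t(1, 2), "at least 2")
})

test_that("p-value formatting mirrors the reporting convention", {
  expect_equal(format_p(0.4969), "0.4969")
  expect_equal(format_p(0.00009), "< 0.0001")
  expect_equal(format_p(0.0001), "0.0001")
})

test_that("summary percentages recompute from their own counts", {
  sim <- generate_session(c(SRC_SUPPRESSED = 2, "NULL" = 3), seed = 61)
  reports <- classify_session(sim$trains, sim$schedule, n_shuffles = 200,
                              seed = 62)
  s <- session_summary(reports)
  expect_equal(s$pct_src, round(100 * s$n_src / s$n_cells, 1))
  expect_equal(s$pct_ssc, round(100 * s$n_ssc / s$n_cells, 1))
  if (s$n_src > 0)
    expect_equal(s$pct_suppressed, round(100 * s$n_suppressed / s$n_src, 1))
})

test_that("the pipeline is deterministic and validates its config", {
  cfg <- list(simulate = list(n_per_class = list(SRC_SUPPRESSED = 2,
                                                 "NULL" = 3)),
              analysis = list(n_shuffles = 150))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_pipeline(cfg, d1, seed = 77)
  r2 <- run_pipeline(cfg, d2, seed = 77)
  for (f in c("report.tsv", "summary.json", "behavior.tsv", "confusion.tsv",
              "manifest.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  expect_equal(r1$summary, r2$summary)

  expect_error(run_pipeline(list(inputs = list(traces = "x.csv")),
                            withr::local_tempdir(), seed = 1),
               "inputs\\$schedule")
})

test_that("pipeline round trip recovers planted classes on strong effects", {
  cfg <- list(simulate = list(n_per_class = list(SRC_SUPPRESSED = 2,
                                                 SSC = 1, "NULL" = 3)),
              analysis = list(n_shuffles = 300))
  d <- withr::local_tempdir()
  res <- run_pipeline(cfg, d, seed = 101)
  conf <- res$confusion
  expect_equal(nrow(conf), 6)
  expect_true(all(conf$correct[conf$planted == "SRC_SUPPRESSED"]))
  expect_true(all(conf$correct[conf$planted == "SSC"]))
  # session files written alongside the analysis
  expect_true(file.exists(file.path(d, "session", "traces.csv")))
  expect_true(file.exists(file.path(d, "session", "ground_truth.tsv")))
})

test_that("a pipeline run from on-disk inputs matches the simulated run", {
  cfg <- list(simulate = list(n_per_class = list(SRC_NOT_SUPPRESSED = 1,
                                                 "NULL" = 2)),
              analysis = list(n_shuffles = 150))
  d <- withr::local_tempdir()
  run_pipeline(cfg, d, seed = 55)
  cfg2 <- list(inputs = list(traces = file.path(d, "session", "traces.csv"),
                             gpio = file.path(d, "session", "gpio.csv"),
                             behavior = file.path(d, "session", "behavior.csv"),
                             schedule = file.path(d, "session", "schedule.yaml")),
               analysis = list(n_shuffles = 150))
  d2 <- withr::local_tempdir()
  run_pipeline(cfg2, d2, seed = 55)
  expect_identical(readLines(file.path(d, "report.tsv")),
                   readLines(file.path(d2, "report.tsv")))
})
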