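test_that("generated schedules respect the protocol constraints", {
  s <- generate_schedule(seed = 1)
  expect_length(s$shock_onsets, 20)
  expect_gte(s$shock_onsets[1], 330)
  itis <- c(s$shock_onsets[1] - 300,
            diff(s$shock_onsets) - s$shock_duration)
  expect_true(all(itis >= 30 & itis <= 60))
  expect_identical(s$off_trials, 1:10)
  expect_identical(s$on_trials, 11:20)
  # LED window = [onset - 1, onset + shock_duration + 1] for ON shocks only
  expect_equal(nrow(s$led_windows), 10)
  expect_equal(s$led_windows[, "start"], s$shock_onsets[11:20] - 1)
  expect_equal(s$led_windows[, "end"], s$shock_onsets[11:20] + 3)
  expect_true(all(s$led_windows >= 0 & s$led_windows <= s$session_length))
})

test_that("degenerate ITI range gives the closed-form onsets", {
  s <- generate_schedule(iti_range = c(45, 45), seed = 3)
  k <- 1:20
  expect_equal(s$shock_onsets, 300 + 45 * k + 2 * (k - 1))
})

test_that("a single shock falls in the OFF half and ON windows are empty", {
  s <- generate_schedule(n_shocks = 1, seed = 2)
  expect_identical(s$off_trials, 1L)
  expect_length(s$on_trials, 0)
  expect_equal(nrow(shock_windows(s, "on")), 0)
})

test_that("shock-phase duration is consistent with a ~15-minute shock period", {
  for (seed in 1:5) {
    s <- generate_schedule(seed = seed)
    phase <- s$shock_onsets[20] + s$shock_duration - 300
    expect_gte(phase, 640)
    expect_lte(phase, 1240)
  }
})

test_that("schedule validation rejects inconsistent inputs", {
  expect_error(generate_schedule(iti_range = c(60, 30)), "inverted")
  expect_error(experiment_schedule(c(400, 350)), "increasing")
  expect_error(experiment_schedule(c(400, 450), off_trials = 1, on_trials = 1),
               "disjoint")
})

test_that("alignment subtracts the trigger time and drops pre-trigger samples", {
  times <- seq(0, 100, by = 0.05)
  tm <- trace_matrix(times, matrix(seq_along(times), ncol = 1),
                     cell_ids = "C1")
  gp <- gpio_record(rep("GPIO-1", 2), c(0, 3.35), c(0, 1))
  al <- align_to_experiment_start(tm, gp)
  expect_true(al$aligned)
  # brute-force scan for the first original sample at or after the trigger
  first_kept <- which(times >= 3.35)[1]
  expect_equal(first_kept, 68)  # 0-based index 67 = 3.35 s x 20 Hz
  expect_equal(al$times[1], times[first_kept] - 3.35)
  expect_equal(unname(al$values[1, 1]), first_kept)

  # trigger at 0: identity
  gp0 <- gpio_record("GPIO-1", 0, 1)
  al0 <- align_to_experiment_start(tm, gp0)
  expect_equal(al0$times, times)
  expect_equal(al0$values, tm$values, ignore_attr = TRUE)
})

test_that("alignment is a rigid shift: sample intervals are preserved", {
  times <- seq(0, 50, by = 0.05)
  tm <- trace_matrix(times, matrix(rnorm(length(times)), ncol = 1),
                     cell_ids = "C1")
  gp <- gpio_record("GPIO-1", 12.3, 1)
  al <- align_to_experiment_start(tm, gp)
  expect_equal(diff(al$times), rep(0.05, length(al$times) - 1))
})

test_that("alignment errors are informative", {
  tm <- trace_matrix(seq(0, 1, by = 0.05), matrix(0, 21, 1), cell_ids = "C1")
  expect_error(align_to_experiment_start(tm, gpio_record("X", 0, 1)),
               "no GPIO events")
  expect_error(
    align_to_experiment_start(tm, gpio_record("GPIO-1", 50, 1)),
    "empty session")
})

test_that("trace CSV round trip is lossless and filters rejected cells", {
  tm <- trace_matrix(seq(0, 2, by = 0.05),
                     matrix(rnorm(41 * 3), ncol = 3),
                     cell_ids = c("C1", "C2", "C3"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tm, path, status = c("accepted", "rejected", "accepted"))
  back <- read_trace_csv(path)
  expect_identical(back$cell_ids, c("C1", "C3"))
  expect_equal(back$values, tm$values[, c(1, 3)], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(back$sampling_rate, 20)

  # no status row: all cells load
  write_trace_csv(tm, path)
  expect_identical(read_trace_csv(path)$cell_ids, c("C1", "C2", "C3"))
})

test_that("behavior log parsing pairs START/STOP and flags unmatched rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,subject,behavior,status",
               "10.0,observer,freezing,START",
               "14.5,observer,freezing,STOP"), path)
  log <- read_behavior_csv(path)
  ep <- attr(log, "epochs")
  expect_equal(nrow(ep), 1)
  expect_equal(c(ep$start, ep$stop), c(10.0, 14.5))

  empty <- behavior_log(data.frame(time = numeric(0), behavior = character(0),
                                   status = character(0)))
  expect_equal(nrow(attr(empty, "epochs")), 0)

  expect_error(behavior_log(data.frame(time = 5, behavior = "freezing",
                                       status = "START")),
               "unmatched START")
  expect_error(behavior_log(data.frame(time = c(1, 2, 3),
                                       behavior = "freezing",
                                       status = c("START", "STOP", "STOP"))),
               "STOP without START")
})

test_that("schedule YAML round trip preserves the timeline", {
  s <- generate_schedule(seed = 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_schedule_yaml(s, path)
  back <- read_schedule_yaml(path)
  expect_equal(back$shock_onsets, s$shock_onsets)
  expect_equal(back$led_windows, s$led_windows, ignore_attr = TRUE)
  expect_equal(back$session_length, s$session_length)
  expect_identical(back$on_trials, s$on_trials)
})

test_that("report writer emits one row per cell plus a count summary", {
  sim <- generate_session(c(SRC_SUPPRESSED = 1, "NULL" = 1), seed = 21)
  reports <- classify_session(sim$trains, sim$schedule, n_shuffles = 100,
                              seed = 4)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_report(reports, tsv, js)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 2)
  expect_named(tab, c("cell_id", "n_spikes", "off_rate", "off_p95", "is_src",
                      "is_ssc", "on_rate", "on_p95", "suppressed",
                      "on_only_src"))
  summ <- jsonlite::read_json(js)
  expect_equal(summ$n_cells, 2)
  expect_equal(summ$n_src, sum(tab$is_src))
})
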