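test_that("window rates count events over half-open windows", {
  w10 <- cbind(seq(0, 90, by = 10), seq(2, 92, by = 10))  # 10 windows x 2 s
  expect_equal(window_spike_rate(numeric(0), w10), 0)
  expect_equal(window_spike_rate(c(0.5, 1, 11, 21.9, 41), w10), 5 / 20)
  # event exactly at a window's end boundary is not counted
  expect_equal(window_spike_rate(2, w10), 0)
  expect_equal(window_spike_rate(0, w10), 1 / 20)
  expect_error(window_spike_rate(1, cbind(3, 3)), "end > start")
})

test_that("circular shift wraps modulo the session and conserves structure", {
  expect_equal(circular_shift(c(100, 1190), 20, 1200), c(10, 120))
  ev <- c(3, 100, 550, 1100)
  expect_equal(circular_shift(ev, 1200, 1200), sort(ev %% 1200))
  # circular inter-event interval multiset is invariant under any shift
  circ_gaps <- function(x, L) sort(diff(c(x, x[1] + L)))
  for (d in c(0.5, 17, 333, 999.9)) {
    expect_equal(circ_gaps(circular_shift(ev, d, 1200), 1200),
                 circ_gaps(ev, 1200))
    expect_length(circular_shift(ev, d, 1200), length(ev))
  }
})

test_that("shuffle null matches a brute-force recount on grid shifts", {
  sched <- fixed_schedule()
  w <- shock_windows(sched, "off")
  ev <- sort(generate_spike_train(
    cell_ground_truth("x", "NULL"), sched, seed = 2)$event_times)
  deltas <- seq(20, 1200, length.out = 50)
  res <- shuffle_null(ev, w, sched$session_length, deltas = deltas)
  expect_equal(res$null_rates,
               brute_force_null(ev, deltas, w, sched$session_length))
  # count conservation for each shift
  for (d in deltas[1:10])
    expect_length(circular_shift(ev, d, sched$session_length), length(ev))
})

test_that("percentile thresholds match an independent sort-and-index oracle", {
  x <- (1:1000) / 1000
  expect_equal(unname(quantile(x, 0.95, type = 7)), oracle_percentile(x, 0.95))
  set.seed(31)
  y <- rpois(1000, 3) / 20
  res <- shuffle_null(numeric(0), cbind(0, 2), 100, n_shuffles = 10, seed = 1)
  expect_equal(res$p95, 0)  # empty train: degenerate null at 0
  expect_equal(oracle_percentile(y, 0.95), unname(quantile(y, 0.95, type = 7)))
  expect_equal(oracle_percentile(y, 0.05), unname(quantile(y, 0.05, type = 7)))
})

test_that("single-event null occupancy matches the geometric probability", {
  # event anywhere on a 10 s circle, window [0, 2): P(rate > 0) = 0.2
  res <- shuffle_null(5, cbind(0, 2), 10, n_shuffles = 4000,
                      shift_range = c(0, 10), seed = 6)
  expect_lt(abs(mean(res$null_rates > 0) - 0.2), 0.03)
})

test_that("shuffle null is deterministic given a seed", {
  sched <- fixed_schedule()
  ev <- c(10, 350, 351, 700, 1000)
  a <- shuffle_null(ev, shock_windows(sched, "off"), sched$session_length,
                    n_shuffles = 100, seed = 44)
  b <- shuffle_null(ev, shock_windows(sched, "off"), sched$session_length,
                    n_shuffles = 100, seed = 44)
  expect_identical(a$null_rates, b$null_rates)
  expect_equal(a$p95, unname(quantile(a$null_rates, 0.95, type = 7)))
  expect_equal(a$p5, unname(quantile(a$null_rates, 0.05, type = 7)))
})

test_that("planted cell classes are recovered from their spike trains", {
  sched <- fixed_schedule()
  sup <- classify_cell(
    generate_spike_train(cell_ground_truth("a", "SRC_SUPPRESSED"), sched,
                         seed = 51),
    sched, n_shuffles = 500, seed = 52)
  expect_true(sup$is_src)
  expect_true(sup$suppressed)
  expect_false(sup$is_ssc)

  nosup <- classify_cell(
    generate_spike_train(cell_ground_truth("b", "SRC_NOT_SUPPRESSED"), sched,
                         seed = 53),
    sched, n_shuffles = 500, seed = 54)
  expect_true(nosup$is_src)
  expect_false(nosup$suppressed)

  ononly <- classify_cell(
    generate_spike_train(cell_ground_truth("c", "SRC_ON_ONLY"), sched,
                         seed = 55),
    sched, n_shuffles = 500, seed = 56)
  expect_true(ononly$on_only_src)
  expect_false(ononly$is_src)

  ssc <- classify_cell(
    generate_spike_train(cell_ground_truth("d", "SSC"), sched, seed = 57),
    sched, n_shuffles = 500, seed = 58)
  expect_true(ssc$is_ssc)
  expect_false(ssc$is_src)

  # an empty train is never significant in either direction
  empty <- classify_cell(spike_train("e", numeric(0)), sched,
                         n_shuffles = 100, seed = 59)
  expect_false(empty$is_src)
  expect_false(empty$is_ssc)
  expect_false(empty$on_only_src)
  expect_true(is.na(empty$suppressed))
})

test_that("suppression is only defined for SRCs and needs ON trials", {
  off_only <- experiment_schedule(seq(330, 700, by = 40),
                                  off_trials = 1:10, on_trials = integer(0))
  rep1 <- classify_cell(spike_train("x", c(331, 371, 411, 451)), off_only,
                        n_shuffles = 100, seed = 3)
  expect_null(rep1$on_result)
  expect_false(rep1$on_only_src)
  expect_error(shock_windows(off_only, "off", "led"), "ON trials")
})

test_that("session summaries reproduce the counts arithmetic", {
  s <- summarize_counts(n_cells = 391, n_src = 27, n_suppressed = 26)
  expect_equal(s$pct_src, 6.9)
  expect_equal(s$pct_suppressed, 96.3)  # 26/27 = 96.296...
  expect_equal(summarize_counts(100, 0)$pct_src, 0)
  expect_true(is.na(summarize_counts(100, 0, 0)$pct_suppressed))
})
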