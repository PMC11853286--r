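#' Mean event rate over a set of windows
#'
#' Events are counted over the union of half-open windows `[start, end)` and
#' divided by the total window duration.
#'
#' @param event_times Sorted event times (s), or a [spike_train()].
#' @param windows 2-column matrix or list of `(start, end)` windows;
#'   must be non-overlapping.
#' @return Events per second (0 for an empty train).
#' @export
window_spike_rate <- function(event_times, windows) {
  if (inherits(event_times, "spike_train")) event_times <- event_times$event_times
  w <- as_windows(windows)
  total <- sum(w[, 2L] - w[, 1L])
  if (total <= 0) stop("total window duration is zero")
  if (length(event_times) == 0L) return(0)
  n <- 0L
  for (i in seq_len(nrow(w)))
    n <- n + sum(in_window(event_times, w[i, 1L], w[i, 2L]))
  n / total
}

#' Circularly shift an event train
#'
#' Each event time `t` maps to `(t + delta) mod session_length`; the event
#' count (and the multiset of circular inter-event intervals) is conserved.
#'
#' @param event_times Event times (s), or a [spike_train()].
#' @param delta Shift (s), non-negative.
#' @param session_length Circle circumference (s).
#' @return Sorted shifted event times.
#' @export
circular_shift <- function(event_times, delta, session_length) {
  if (inherits(event_times, "spike_train")) event_times <- event_times$event_times
  if (delta < 0) stop("delta must be non-negative")
  sort((event_times + delta) %% session_length)
}

#' Temporal-shift shuffle null for a window rate
#'
#' Builds the null distribution of the shock-window event rate by circularly
#' shifting the whole event train `n_shuffles` times by increments drawn
#' uniformly from `shift_range` (wrapping modulo the session length, which
#' conserves the event count) and recomputing the window rate after each
#' shift. The 95th and 5th percentiles of the null (linear interpolation
#' between order statistics, R quantile type 7) are the significance
#' thresholds for shock-responding and shock-suppressed calls.
#'
#' @param train A [spike_train()] (or bare event-time vector).
#' @param windows Analysis windows, as in [window_spike_rate()].
#' @param session_length Session length (s).
#' @param n_shuffles Number of shifts; default 1000.
#' @param shift_range Uniform shift bounds (s); default `c(20, 1200)`.
#' @param seed RNG seed (shifts are deterministic given the seed).
#' @param deltas Optional explicit shift vector (overrides random draws);
#'   used for grid-based cross-checks.
#' @param condition Label (`"OFF"`/`"ON"`) carried into the result.
#' @return An object of class `shuffle_result` with fields `observed_rate`,
#'   `null_rates`, `p95`, `p5`, `n_shuffles`, `shift_range`.
#' @export
shuffle_null <- function(train, windows, session_length, n_shuffles = 1000,
                         shift_range = c(20, 1200), seed = NULL,
                         deltas = NULL, condition = NA_character_) {
  ev <- if (inherits(train, "spike_train")) train$event_times else as.numeric(train)
  cell_id <- if (inherits(train, "spike_train")) train$cell_id else NA_character_
  w <- as_windows(windows)
  if (sum(w[, 2L] - w[, 1L]) >= session_length)
    stop("windows must not cover the whole session")
  if (shift_range[1L] < 0) stop("shift_range lower bound must be non-negative")
  if (is.null(deltas)) {
    deltas <- with_seed(seed,
      stats::runif(n_shuffles, shift_range[1L], shift_range[2L]))
  } else {
    n_shuffles <- length(deltas)
  }
  observed <- window_spike_rate(ev, w)
  total <- sum(w[, 2L] - w[, 1L])
  if (length(ev) == 0L) {
    null_rates <- rep(0, n_shuffles)
  } else {
    # shifted[i, j] = event i under shift j; count per shift across windows
    shifted <- (outer(ev, deltas, `+`)) %% session_length
    counts <- integer(n_shuffles)
    for (i in seq_len(nrow(w)))
      counts <- counts + colSums(shifted >= w[i, 1L] & shifted < w[i, 2L])
    null_rates <- counts / total
  }
  structure(list(cell_id = cell_id, condition = condition,
                 observed_rate = observed, null_rates = null_rates,
                 p95 = unname(stats::quantile(null_rates, 0.95, type = 7)),
                 p5 = unname(stats::quantile(null_rates, 0.05, type = 7)),
                 n_shuffles = n_shuffles, shift_range = shift_range),
            class = "shuffle_result")
}

#' Classify one cell as shock-responding / shock-suppressed
#'
#' A cell is a shock-responding cell (SRC) when its observed rate over the
#' light-OFF shock windows strictly exceeds the 95th percentile of its
#' shuffle null, and a shock-suppressed cell (SSC) when that rate falls
#' strictly below the null's 5th percentile. For SRCs a fresh shuffle null is
#' computed over the light-ON shock windows: the SRC is *suppressed* when its
#' ON-window rate no longer exceeds the ON null's 95th percentile. A cell
#' that is not an SRC but whose ON-window rate exceeds the ON null's 95th
#' percentile is flagged `on_only_src`. An empty train is never significant
#' (its observed rate 0 cannot strictly exceed or fall below a degenerate
#' null at 0).
#'
#' @param train A [spike_train()] aligned to the schedule.
#' @param schedule An [experiment_schedule()].
#' @param n_shuffles,shift_range As in [shuffle_null()].
#' @param seed Master seed for this cell; OFF and ON nulls use sub-seeds.
#' @param window_kind `"shock"` (2 s shock windows, the default analysis
#'   windows) or `"led"` (4 s LED windows) for the ON condition.
#' @return An object of class `cell_report`.
#' @export
classify_cell <- function(train, schedule, n_shuffles = 1000,
                          shift_range = c(20, 1200), seed = NULL,
                          window_kind = c("shock", "led")) {
  window_kind <- match.arg(window_kind)
  off_w <- shock_windows(schedule, "off")
  if (nrow(off_w) == 0L) stop("schedule has no OFF trials")
  off <- shuffle_null(train, off_w, schedule$session_length,
                      n_shuffles = n_shuffles, shift_range = shift_range,
                      seed = derive_seed(seed, 1L), condition = "OFF")
  is_src <- off$observed_rate > off$p95
  is_ssc <- off$observed_rate < off$p5

  on <- NULL
  suppressed <- NA
  on_only <- FALSE
  if (length(schedule$on_trials) > 0L) {
    on_w <- if (window_kind == "led") shock_windows(schedule, "on", "led")
            else shock_windows(schedule, "on")
    on <- shuffle_null(train, on_w, schedule$session_length,
                       n_shuffles = n_shuffles, shift_range = shift_range,
                       seed = derive_seed(seed, 2L), condition = "ON")
    on_sig <- on$observed_rate > on$p95
    if (is_src) suppressed <- !on_sig
    on_only <- !is_src && on_sig
  }
  structure(list(cell_id = train$cell_id,
                 n_spikes = length(train$event_times),
                 is_src = is_src, is_ssc = is_ssc,
                 suppressed = suppressed, on_only_src = on_only,
                 off_result = off, on_result = on),
            class = "cell_report")
}

#' @export
print.cell_report <- function(x, ...) {
  lab <- if (x$is_src) {
    paste0("SRC", if (isTRUE(x$suppressed)) " (suppressed)" else
      if (identical(x$suppressed, FALSE)) " (not suppressed)" else "")
  } else if (x$is_ssc) "SSC" else if (x$on_only_src) "ON-only SRC" else "none"
  cat(sprintf("cell_report '%s': %s [%d events, OFF rate %.4g vs p95 %.4g]\n",
              x$cell_id, lab, x$n_spikes, x$off_result$observed_rate,
              x$off_result$p95))
  invisible(x)
}

#' Classify every cell of a session
#'
#' @param trains List of [spike_train()] objects.
#' @param schedule An [experiment_schedule()].
#' @param n_shuffles,shift_range,window_kind As in [classify_cell()].
#' @param seed Master seed; each cell gets a deterministic sub-seed.
#' @return List of `cell_report` objects.
#' @export
classify_session <- function(trains, schedule, n_shuffles = 1000,
                             shift_range = c(20, 1200), seed = NULL,
                             window_kind = "shock") {
  lapply(seq_along(trains), function(i)
    classify_cell(trains[[i]], schedule, n_shuffles = n_shuffles,
                  shift_range = shift_range,
                  seed = derive_seed(seed, 100L + i),
                  window_kind = window_kind))
}

#' Session-level classification counts
#'
#' Totals and percentages in the style of the session summary figures:
#' number of cells, SRCs (with percentage of all cells), suppressed SRCs
#' (with percentage of SRCs), SSCs and ON-only SRCs. Percentages are
#' recomputed from the counts and rounded to one decimal.
#'
#' @param reports List of `cell_report` objects.
#' @return Named list of counts and percentages.
#' @export
session_summary <- function(reports) {
  if (length(reports) == 0L) stop("no cell reports to summarize")
  df <- report_table(reports)
  summarize_counts(n_cells = nrow(df),
                   n_src = sum(df$is_src),
                   n_suppressed = sum(df$is_src & df$suppressed %in% TRUE),
                   n_ssc = sum(df$is_ssc),
                   n_on_only = sum(df$on_only_src))
}

#' @rdname session_summary
#' @param n_cells,n_src,n_suppressed,n_ssc,n_on_only Raw counts.
#' @export
summarize_counts <- function(n_cells, n_src, n_suppressed = NA_integer_,
                             n_ssc = 0L, n_on_only = 0L) {
  list(n_cells = n_cells,
       n_src = n_src,
       pct_src = pct1(n_src, n_cells),
       n_suppressed = n_suppressed,
       pct_suppressed = if (is.na(n_suppressed) || n_src == 0) NA_real_
                        else pct1(n_suppressed, n_src),
       n_ssc = n_ssc,
       pct_ssc = pct1(n_ssc, n_cells),
       n_on_only = n_on_only)
}
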