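#' Extract accepted freezing bouts from an event log
#'
#' Abutting freezing epochs (zero gap) are merged first; epochs with duration
#' strictly greater than `min_duration` are retained as bouts, sorted by
#' start time.
#'
#' @param log A `behavior_log` (see [behavior_log()]).
#' @param behavior Behavior label to extract; default `"freezing"`.
#' @param min_duration Strict duration threshold (s); default 2.
#' @return data.frame with columns `start`, `end`, `duration`.
#' @export
extract_bouts <- function(log, behavior = "freezing", min_duration = 2) {
  ep <- attr(log, "epochs")
  ep <- ep[ep$behavior == behavior, , drop = FALSE]
  if (nrow(ep) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0)))
  ep <- ep[order(ep$start), , drop = FALSE]
  # merge abutting epochs (gap == 0) so a split record counts as one bout
  starts <- ep$start[1L]; ends <- ep$stop[1L]
  for (i in seq_len(nrow(ep))[-1L]) {
    k <- length(starts)
    if (ep$start[i] <= ends[k]) {
      ends[k] <- max(ends[k], ep$stop[i])
    } else {
      starts <- c(starts, ep$start[i]); ends <- c(ends, ep$stop[i])
    }
  }
  out <- data.frame(start = starts, end = ends, duration = ends - starts)
  out[out$duration > min_duration, , drop = FALSE]
}

#' Freezing metrics for one condition period
#'
#' Bouts belong to a period by their *start* time (a bout straddling the
#' period boundary counts once, toward the period in which it began, with
#' its full duration credited there unless `clip_to_period = TRUE`).
#'
#' @param bouts data.frame from [extract_bouts()].
#' @param period Length-2 numeric, half-open `[start, end)` condition period.
#' @param shock_windows Shock windows of the period (2-column matrix), used
#'   for the mean duration of bouts that begin inside a shock window.
#' @param condition Label carried into the result.
#' @param clip_to_period Clip bout durations at the period end before
#'   summing? Default `FALSE`.
#' @return List: `condition`, `period`, `n_bouts`, `total_freeze_s`,
#'   `pct_freeze`, `mean_bout_s`, `shock_onset_bout_mean_s`,
#'   `n_shock_onset_bouts`, `undefined_mean` (TRUE when no bouts).
#' @export
condition_metrics <- function(bouts, period, shock_windows = NULL,
                              condition = NA_character_,
                              clip_to_period = FALSE) {
  period <- as.numeric(period)
  if (period[2L] <= period[1L]) stop("empty condition period")
  sel <- in_window(bouts$start, period[1L], period[2L])
  b <- bouts[sel, , drop = FALSE]
  dur <- if (clip_to_period) pmin(b$end, period[2L]) - b$start else b$duration
  n <- nrow(b)
  total <- sum(dur)
  sw <- as_windows(shock_windows)
  in_shock <- rep(FALSE, n)
  for (i in seq_len(nrow(sw)))
    in_shock <- in_shock | in_window(b$start, sw[i, 1L], sw[i, 2L])
  list(condition = condition,
       period = period,
       n_bouts = n,
       total_freeze_s = total,
       pct_freeze = 100 * total / (period[2L] - period[1L]),
       mean_bout_s = if (n > 0L) total / n else 0,
       shock_onset_bout_mean_s = if (any(in_shock)) mean(dur[in_shock]) else 0,
       n_shock_onset_bouts = sum(in_shock),
       undefined_mean = n == 0L)
}

#' Default OFF/ON comparison periods of a schedule
#'
#' OFF: from the first light-OFF shock onset to the start of the first LED
#' window; ON: from the first LED window start to the session end. These
#' boundaries are a documented convention, configurable by passing explicit
#' periods to [condition_metrics()].
#'
#' @param schedule An [experiment_schedule()].
#' @return List with `off` and `on` periods (length-2 numerics).
#' @export
condition_periods <- function(schedule) {
  if (length(schedule$on_trials) == 0L || nrow(schedule$led_windows) == 0L)
    stop("schedule has no ON trials; no OFF/ON split exists")
  on_start <- min(schedule$led_windows[, 1L])
  off_start <- schedule$shock_onsets[min(schedule$off_trials)]
  list(off = c(off_start, on_start),
       on = c(on_start, schedule$session_length))
}

#' Freezing metrics for both conditions of a session
#'
#' @param log A `behavior_log`.
#' @param schedule An [experiment_schedule()].
#' @param min_duration Bout threshold (s).
#' @return List with `off` and `on` [condition_metrics()] results and the
#'   accepted `bouts`.
#' @export
session_behavior <- function(log, schedule, min_duration = 2) {
  bouts <- extract_bouts(log, min_duration = min_duration)
  per <- condition_periods(schedule)
  list(off = condition_metrics(bouts, per$off, shock_windows(schedule, "off"),
                               condition = "OFF"),
       on = condition_metrics(bouts, per$on, shock_windows(schedule, "on"),
                              condition = "ON"),
       bouts = bouts)
}

#' Paired comparison of a freezing metric across sessions
#'
#' Two-tailed paired t-test on per-session OFF vs ON values of one metric.
#'
#' @param sessions List of [session_behavior()] results (length >= 2).
#' @param metric One of `"pct_freeze"`, `"n_bouts"`, `"mean_bout_s"`,
#'   `"shock_onset_bout_mean_s"`, `"total_freeze_s"`.
#' @return A [paired_t()] result.
#' @export
compare_conditions <- function(sessions,
                               metric = c("pct_freeze", "n_bouts",
                                          "mean_bout_s",
                                          "shock_onset_bout_mean_s",
                                          "total_freeze_s")) {
  metric <- match.arg(metric)
  if (length(sessions) < 2L) stop("need at least 2 sessions for a paired test")
  x <- vapply(sessions, function(s) as.numeric(s$off[[metric]]), numeric(1))
  y <- vapply(sessions, function(s) as.numeric(s$on[[metric]]), numeric(1))
  paired_t(x, y)
}
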