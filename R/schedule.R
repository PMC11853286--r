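#' Experiment schedule for an observational-fear session
#'
#' Describes the timeline of one session: a habituation period followed by a
#' train of brief foot shocks delivered to the demonstrator, with the
#' inhibitory-opsin LED on for the second half of the shocks. All times are in
#' seconds from experiment start (time 0 = GPIO trigger); analysis windows are
#' half-open `[start, end)`.
#'
#' @param shock_onsets Strictly increasing shock-onset times (s).
#' @param shock_duration Shock duration (s); default 2.
#' @param habituation_duration Habituation period length (s); default 300.
#' @param off_trials,on_trials Integer indices (1-based) of light-OFF and
#'   light-ON shocks. Defaults: first `ceiling(n/2)` shocks OFF, rest ON.
#' @param led_windows Optional 2-column matrix of LED `(start, end)` windows;
#'   by default one window per ON shock spanning `[onset - 1,
#'   onset + shock_duration + 1]` (the LED leads and trails the shock by 1 s).
#' @param session_length Total session length (s). Default: last shock offset
#'   plus a 30 s tail.
#'
#' @return An object of class `experiment_schedule`.
#' @export
experiment_schedule <- function(shock_onsets,
                                shock_duration = 2,
                                habituation_duration = 300,
                                off_trials = NULL,
                                on_trials = NULL,
                                led_windows = NULL,
                                session_length = NULL) {
  shock_onsets <- as.numeric(shock_onsets)
  n <- length(shock_onsets)
  if (n < 1L) stop("at least one shock onset is required")
  if (any(diff(shock_onsets) <= 0)) stop("shock_onsets must be strictly increasing")
  if (shock_onsets[1L] < habituation_duration)
    stop("first shock onset lies inside the habituation period")

  if (is.null(off_trials) && is.null(on_trials)) {
    off_trials <- seq_len(ceiling(n / 2))
    on_trials <- setdiff(seq_len(n), off_trials)
  } else {
    off_trials <- as.integer(off_trials)
    on_trials <- as.integer(on_trials)
  }
  if (length(intersect(off_trials, on_trials)) > 0L)
    stop("off_trials and on_trials must be disjoint")
  if (!setequal(union(off_trials, on_trials), seq_len(n)))
    stop("off_trials and on_trials must together cover all shocks")

  if (is.null(led_windows)) {
    led_windows <- cbind(start = shock_onsets[on_trials] - 1,
                         end = shock_onsets[on_trials] + shock_duration + 1)
  } else {
    led_windows <- as_windows(led_windows)
  }

  if (is.null(session_length))
    session_length <- shock_onsets[n] + shock_duration + 30
  if (session_length < shock_onsets[n] + shock_duration)
    stop("session_length must cover the last shock")
  if (nrow(led_windows) > 0L &&
      (any(led_windows[, 1L] < 0) || any(led_windows[, 2L] > session_length)))
    stop("LED windows must lie within [0, session_length]")

  structure(list(habituation_start = 0,
                 habituation_duration = habituation_duration,
                 shock_onsets = shock_onsets,
                 shock_duration = shock_duration,
                 led_windows = led_windows,
                 off_trials = sort(off_trials),
                 on_trials = sort(on_trials),
                 session_length = session_length),
            class = "experiment_schedule")
}

#' Shock (or LED) analysis windows of a schedule
#'
#' @param schedule An [experiment_schedule()].
#' @param condition `"off"`, `"on"`, or `"all"` shocks.
#' @param kind `"shock"` for the 2 s shock windows, `"led"` for the 4 s LED
#'   windows (ON trials only).
#' @return 2-column matrix of half-open `(start, end)` windows.
#' @export
shock_windows <- function(schedule, condition = c("off", "on", "all"),
                          kind = c("shock", "led")) {
  condition <- match.arg(condition)
  kind <- match.arg(kind)
  if (kind == "led") {
    if (condition == "off") stop("LED windows exist only for ON trials")
    return(as_windows(schedule$led_windows))
  }
  idx <- switch(condition,
                off = schedule$off_trials,
                on = schedule$on_trials,
                all = seq_along(schedule$shock_onsets))
  if (length(idx) == 0L)
    return(as_windows(NULL))
  cbind(start = schedule$shock_onsets[idx],
        end = schedule$shock_onsets[idx] + schedule$shock_duration)
}

#' Generate a randomized shock schedule
#'
#' Builds the default protocol: a 300 s habituation followed by `n_shocks`
#' 2 s shocks separated by inter-trial intervals drawn uniformly from
#' `iti_range` (an ITI precedes each shock, including the first). The LED is
#' attached to the second half of the shocks.
#'
#' @param n_shocks Number of shocks (default 20).
#' @param iti_range Length-2 numeric, uniform ITI bounds in seconds
#'   (default `c(30, 60)`).
#' @param shock_duration,habituation_duration See [experiment_schedule()].
#' @param seed RNG seed for the ITI draws.
#' @return An [experiment_schedule()].
#' @export
generate_schedule <- function(n_shocks = 20, iti_range = c(30, 60),
                              shock_duration = 2, habituation_duration = 300,
                              seed = NULL) {
  if (n_shocks < 1L) stop("n_shocks must be at least 1")
  if (iti_range[2L] < iti_range[1L]) stop("iti_range is inverted")
  itis <- with_seed(seed, stats::runif(n_shocks, iti_range[1L], iti_range[2L]))
  onsets <- habituation_duration + cumsum(itis) +
    shock_duration * (seq_len(n_shocks) - 1L)
  experiment_schedule(onsets, shock_duration = shock_duration,
                      habituation_duration = habituation_duration)
}

#' @export
print.experiment_schedule <- function(x, ...) {
  cat(sprintf("experiment_schedule: %d shocks (%g s each), habituation %g s\n",
              length(x$shock_onsets), x$shock_duration, x$habituation_duration))
  cat(sprintf("  OFF trials: %s\n", paste(x$off_trials, collapse = " ")))
  cat(sprintf("  ON trials:  %s\n", paste(x$on_trials, collapse = " ")))
  cat(sprintf("  session length: %.1f s\n", x$session_length))
  invisible(x)
}

# serialize/deserialize (plain lists for YAML round trips)
schedule_to_list <- function(schedule) {
  list(habituation_duration = schedule$habituation_duration,
       shock_onsets = as.numeric(schedule$shock_onsets),
       shock_duration = schedule$shock_duration,
       off_trials = as.integer(schedule$off_trials),
       on_trials = as.integer(schedule$on_trials),
       led_windows = lapply(seq_len(nrow(schedule$led_windows)), function(i)
         as.numeric(schedule$led_windows[i, ])),
       session_length = schedule$session_length)
}

schedule_from_list <- function(x) {
  led <- if (length(x$led_windows)) as_windows(x$led_windows) else NULL
  experiment_schedule(x$shock_onsets,
                      shock_duration = x$shock_duration,
                      habituation_duration = x$habituation_duration,
                      off_trials = x$off_trials,
                      on_trials = x$on_trials,
                      led_windows = led,
                      session_length = x$session_length)
}

#' Read / write a schedule as YAML
#' @param schedule An [experiment_schedule()].
#' @param path File path.
#' @return `read_schedule_yaml` returns an [experiment_schedule()];
#'   `write_schedule_yaml` returns `path` invisibly.
#' @export
write_schedule_yaml <- function(schedule, path) {
  yaml::write_yaml(schedule_to_list(schedule), path)
  invisible(path)
}

#' @rdname write_schedule_yaml
#' @export
read_schedule_yaml <- function(path) schedule_from_list(yaml::read_yaml(path))
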