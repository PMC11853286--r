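#' Ground-truth description of a simulated cell
#'
#' Each simulated cell belongs to one of five classes with class-appropriate
#' event rates: `SRC_SUPPRESSED` (elevated rate in light-OFF shock windows,
#' back to baseline during light-ON shocks), `SRC_NOT_SUPPRESSED` (elevated
#' in both conditions), `SRC_ON_ONLY` (elevated only during light-ON shocks),
#' `SSC` (an active cell that falls silent during shocks), and `NULL`
#' (homogeneous Poisson throughout).
#'
#' Default rates: SRC-type cells fire at 0.05 events/s baseline and
#' 2 events/s in their responsive shock windows (a 40-fold effect); NULL
#' cells at 0.1 events/s everywhere; SSC cells at 0.5 events/s baseline and
#' 0 in shock windows — a suppressed cell is only detectable against a null
#' whose 5th percentile is positive, which needs several baseline events per
#' 20 s of shock window.
#'
#' @param cell_id Label.
#' @param klass One of `"SRC_SUPPRESSED"`, `"SRC_NOT_SUPPRESSED"`,
#'   `"SRC_ON_ONLY"`, `"SSC"`, `"NULL"`.
#' @param baseline_rate,shock_rate_off,shock_rate_on Events/s; `NULL` selects
#'   the class default.
#' @return An object of class `cell_ground_truth`.
#' @export
cell_ground_truth <- function(cell_id, klass,
                              baseline_rate = NULL,
                              shock_rate_off = NULL,
                              shock_rate_on = NULL) {
  klass <- match.arg(klass, c("SRC_SUPPRESSED", "SRC_NOT_SUPPRESSED",
                              "SRC_ON_ONLY", "SSC", "NULL"))
  defaults <- switch(klass,
    SRC_SUPPRESSED     = c(0.05, 2.0, 0.05),
    SRC_NOT_SUPPRESSED = c(0.05, 2.0, 2.0),
    SRC_ON_ONLY        = c(0.05, 0.05, 2.0),
    SSC                = c(0.5, 0.0, 0.5),
    "NULL"             = c(0.1, 0.1, 0.1))
  if (is.null(baseline_rate)) baseline_rate <- defaults[1L]
  if (is.null(shock_rate_off)) shock_rate_off <- defaults[2L]
  if (is.null(shock_rate_on)) shock_rate_on <- defaults[3L]
  if (any(c(baseline_rate, shock_rate_off, shock_rate_on) < 0))
    stop("rates must be non-negative")
  structure(list(cell_id = as.character(cell_id), klass = klass,
                 baseline_rate = baseline_rate,
                 shock_rate_off = shock_rate_off,
                 shock_rate_on = shock_rate_on),
            class = "cell_ground_truth")
}

#' GCaMP6f-like transient kernel parameters
#'
#' The rendered fluorescence response to one event is a difference of
#' exponentials, `exp(-t/decay_tau) - exp(-t/rise_tau)`, normalized to peak
#' amplitude `amplitude`; defaults are typical of GCaMP6f (fast rise, ~0.5 s
#' decay). With the default `amplitude / noise_sd = 6` transient peaks sit
#' comfortably above a 2-SD detection threshold.
#'
#' @param rise_tau,decay_tau Rise and decay time constants (s);
#'   `rise_tau < decay_tau`.
#' @param amplitude Peak transient amplitude (fluorescence units).
#' @param noise_sd Gaussian sample-noise SD (fluorescence units).
#' @param baseline_level Constant baseline fluorescence.
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(rise_tau = 0.08, decay_tau = 0.5,
                          amplitude = 6, noise_sd = 1, baseline_level = 10) {
  if (rise_tau >= decay_tau) stop("rise_tau must be smaller than decay_tau")
  if (rise_tau <= 0) stop("time constants must be positive")
  structure(list(rise_tau = rise_tau, decay_tau = decay_tau,
                 amplitude = amplitude, noise_sd = noise_sd,
                 baseline_level = baseline_level),
            class = "kernel_params")
}

# unit-peak kernel evaluated at lags t >= 0
transient_kernel <- function(t, kp) {
  tr <- kp$rise_tau; td <- kp$decay_tau
  tpk <- tr * td / (td - tr) * log(td / tr)
  peak <- exp(-tpk / td) - exp(-tpk / tr)
  ifelse(t < 0, 0, (exp(-t / td) - exp(-t / tr)) / peak)
}

# session partitioned into contiguous segments with per-segment rates:
# baseline everywhere except OFF shock windows (rate_off) and ON shock
# windows (rate_on)
rate_segments <- function(truth, schedule) {
  segs <- data.frame(start = 0, end = schedule$session_length,
                     rate = truth$baseline_rate)
  add <- function(segs, w, rate) {
    for (i in seq_len(nrow(w))) {
      s <- w[i, 1L]; e <- w[i, 2L]
      hit <- which(segs$start < e & segs$end > s)
      pieces <- lapply(hit, function(j) {
        out <- list()
        if (segs$start[j] < s)
          out[[length(out) + 1L]] <- data.frame(start = segs$start[j], end = s,
                                                rate = segs$rate[j])
        out[[length(out) + 1L]] <- data.frame(start = max(segs$start[j], s),
                                              end = min(segs$end[j], e),
                                              rate = rate)
        if (segs$end[j] > e)
          out[[length(out) + 1L]] <- data.frame(start = e, end = segs$end[j],
                                                rate = segs$rate[j])
        do.call(rbind, out)
      })
      segs <- rbind(segs[-hit, , drop = FALSE], do.call(rbind, pieces))
      segs <- segs[order(segs$start), , drop = FALSE]
    }
    segs
  }
  segs <- add(segs, shock_windows(schedule, "off"), truth$shock_rate_off)
  if (length(schedule$on_trials) > 0L)
    segs <- add(segs, shock_windows(schedule, "on"), truth$shock_rate_on)
  rownames(segs) <- NULL
  segs
}

#' Simulate a spike train for a ground-truth cell
#'
#' Piecewise-homogeneous Poisson process: the event rate is the cell's
#' baseline rate everywhere except inside the schedule's shock windows,
#' where it switches to the class-appropriate OFF/ON rate. The event count in
#' any window is Poisson with mean `rate x duration`.
#'
#' @param truth A [cell_ground_truth()].
#' @param schedule An [experiment_schedule()].
#' @param seed RNG seed.
#' @return A [spike_train()] (times aligned to the experiment).
#' @export
generate_spike_train <- function(truth, schedule, seed = NULL) {
  segs <- rate_segments(truth, schedule)
  ev <- with_seed(seed, {
    out <- lapply(seq_len(nrow(segs)), function(i) {
      len <- segs$end[i] - segs$start[i]
      n <- stats::rpois(1L, segs$rate[i] * len)
      if (n == 0L) numeric(0) else stats::runif(n, segs$start[i], segs$end[i])
    })
    sort(unlist(out))
  })
  spike_train(truth$cell_id, ev)
}

#' Render a fluorescence trace from an event train
#'
#' Convolves the event train with the difference-of-exponentials transient
#' kernel, adds the baseline level and i.i.d. Gaussian noise, and samples on
#' the uniform acquisition grid.
#'
#' @param event_times Event times (s), or a [spike_train()].
#' @param kernel A [kernel_params()].
#' @param session_length Trace duration (s).
#' @param sampling_rate Hz; default 20.
#' @param seed RNG seed for the noise.
#' @return List with `times` and `values`.
#' @export
render_trace <- function(event_times, kernel, session_length,
                         sampling_rate = 20, seed = NULL) {
  if (inherits(event_times, "spike_train")) event_times <- event_times$event_times
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  n <- round(session_length * sampling_rate)
  times <- (seq_len(n) - 1L) / sampling_rate
  v <- rep(kernel$baseline_level, n)
  kern_len <- ceiling(8 * kernel$decay_tau * sampling_rate)  # kernel support, samples
  for (te in event_times) {
    i0 <- floor(te * sampling_rate) + 1L
    if (i0 > n) next
    idx <- i0:min(n, i0 + kern_len)
    v[idx] <- v[idx] + kernel$amplitude * transient_kernel(times[idx] - te, kernel)
  }
  if (kernel$noise_sd > 0)
    v <- v + with_seed(seed, stats::rnorm(n, 0, kernel$noise_sd))
  list(times = times, values = v)
}

#' Simulate a freezing-behavior event log
#'
#' Two-state alternating-renewal process (move/freeze) with exponential
#' state durations; at each shock onset a moving animal starts a freezing
#' bout within the 2 s shock window with probability `p_shock_freeze`. This
#' exists to exercise the behavior metrics, not to model real freezing
#' dynamics.
#'
#' @param schedule An [experiment_schedule()].
#' @param mean_freeze,mean_move Mean state durations (s).
#' @param p_shock_freeze Probability that a shock interrupts movement with a
#'   freezing bout starting inside the shock window.
#' @param seed RNG seed.
#' @return A `behavior_log` (see [behavior_log()]).
#' @export
generate_behavior_log <- function(schedule, mean_freeze = 6, mean_move = 8,
                                  p_shock_freeze = 0.6, seed = NULL) {
  L <- schedule$session_length
  onsets <- schedule$shock_onsets
  epochs <- with_seed(seed, {
    t <- 0; freezing <- FALSE
    starts <- numeric(0); stops <- numeric(0)
    while (t < L) {
      dur <- stats::rexp(1L, 1 / if (freezing) mean_freeze else mean_move)
      t_end <- t + dur
      if (!freezing) {
        hit <- onsets[onsets >= t & onsets < t_end]
        if (length(hit) > 0L && stats::runif(1L) < p_shock_freeze)
          t_end <- hit[1L] + stats::runif(1L, 0, schedule$shock_duration)
      } else {
        starts <- c(starts, t); stops <- c(stops, min(t_end, L))
      }
      freezing <- !freezing
      t <- t_end
    }
    data.frame(start = starts, stop = stops)
  })
  epochs <- epochs[epochs$stop > epochs$start, , drop = FALSE]
  if (nrow(epochs) == 0L)
    return(behavior_log(data.frame(time = numeric(0), subject = character(0),
                                   behavior = character(0), status = character(0))))
  behavior_log(data.frame(
    time = as.vector(rbind(epochs$start, epochs$stop)),
    subject = "observer",
    behavior = "freezing",
    status = rep(c("START", "STOP"), nrow(epochs))))
}

#' Simulate a complete observational-fear session
#'
#' Generates a schedule, ground-truth cells, their spike trains, rendered
#' raw (unaligned) fluorescence traces whose acquisition clock starts
#' `gpio_offset` seconds before the experiment, a GPIO record with the
#' experiment-start trigger, and a freezing-behavior log. All randomness is
#' derived from the single master `seed`, so identical seeds give identical
#' sessions.
#'
#' @param n_per_class Named integer vector/list, cells per class, e.g.
#'   `c(SRC_SUPPRESSED = 10, "NULL" = 40)`.
#' @param schedule Optional [experiment_schedule()]; generated when `NULL`.
#' @param kernel A [kernel_params()].
#' @param gpio_offset Acquisition-clock time of the experiment start (s).
#' @param sampling_rate Hz.
#' @param seed Master seed.
#' @return List with `traces` (raw, unaligned [trace_matrix()]), `gpio`,
#'   `schedule`, `behavior`, `truth` (list of [cell_ground_truth()]), and
#'   `trains` (the planted aligned [spike_train()]s).
#' @export
generate_session <- function(n_per_class, schedule = NULL,
                             kernel = kernel_params(), gpio_offset = 5,
                             sampling_rate = 20, seed = NULL) {
  n_per_class <- unlist(n_per_class)
  if (length(n_per_class) == 0L || sum(n_per_class) == 0L)
    stop("n_per_class must request at least one cell")
  if (is.null(schedule))
    schedule <- generate_schedule(seed = derive_seed(seed, 1L))

  klasses <- rep(names(n_per_class), times = n_per_class)
  ids <- paste0("C", sprintf("%03d", seq_along(klasses)))
  truth <- Map(cell_ground_truth, ids, klasses)
  names(truth) <- ids

  trains <- lapply(seq_along(truth), function(i)
    generate_spike_train(truth[[i]], schedule, seed = derive_seed(seed, 10L + i)))
  names(trains) <- ids

  raw_len <- gpio_offset + schedule$session_length
  mat <- vapply(seq_along(trains), function(i) {
    render_trace(trains[[i]]$event_times + gpio_offset, kernel, raw_len,
                 sampling_rate = sampling_rate,
                 seed = derive_seed(seed, 5000L + i))$values
  }, numeric(round(raw_len * sampling_rate)))
  times <- (seq_len(nrow(mat)) - 1L) / sampling_rate
  traces <- trace_matrix(times, mat, cell_ids = ids,
                         sampling_rate = sampling_rate, aligned = FALSE)

  gpio <- gpio_record(channel = c("GPIO-1", "GPIO-1", "GPIO-1"),
                      timestamps = c(0, gpio_offset,
                                     gpio_offset + schedule$session_length),
                      values = c(0, 1, 0))
  behavior <- generate_behavior_log(schedule, seed = derive_seed(seed, 3L))
  list(traces = traces, gpio = gpio, schedule = schedule,
       behavior = behavior, truth = truth, trains = trains)
}

#' Write a simulated session to disk
#'
#' Writes `traces.csv`, `gpio.csv`, `behavior.csv`, `schedule.yaml` and
#' `ground_truth.tsv` under `dir`.
#'
#' @param session Result of [generate_session()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trace_csv(session$traces, file.path(dir, "traces.csv"),
                  status = rep("accepted", length(session$traces$cell_ids)))
  write_gpio_csv(session$gpio, file.path(dir, "gpio.csv"))
  write_behavior_csv(session$behavior, file.path(dir, "behavior.csv"))
  write_schedule_yaml(session$schedule, file.path(dir, "schedule.yaml"))
  tt <- do.call(rbind, lapply(session$truth, function(x)
    data.frame(cell_id = x$cell_id, klass = x$klass,
               baseline_rate = x$baseline_rate,
               shock_rate_off = x$shock_rate_off,
               shock_rate_on = x$shock_rate_on)))
  utils::write.table(tt, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
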