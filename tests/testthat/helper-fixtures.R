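# shared fixtures: small deterministic schedules and trains

# schedule with fixed 45 s ITIs: onset_k = 300 + 45k + 2(k-1)
fixed_schedule <- function(n_shocks = 20, shock_duration = 2) {
  k <- seq_len(n_shocks)
  experiment_schedule(300 + 45 * k + shock_duration * (k - 1),
                      shock_duration = shock_duration)
}

# noiseless kernel for exact-recovery tests
quiet_kernel <- function(...) kernel_params(noise_sd = 0, ...)

# BORIS-style freezing log from a matrix/list of (start, stop) epochs
freeze_log <- function(epochs) {
  ep <- do.call(rbind, lapply(epochs, function(e) as.numeric(e)))
  behavior_log(data.frame(
    time = as.vector(rbind(ep[, 1], ep[, 2])),
    behavior = "freezing",
    status = rep(c("START", "STOP"), nrow(ep))))
}

# independent brute-force recount of shuffled window rates
brute_force_null <- function(event_times, deltas, windows, session_length) {
  w <- as_windows(windows)
  total <- sum(w[, 2] - w[, 1])
  vapply(deltas, function(d) {
    shifted <- (event_times + d) %% session_length
    n <- 0L
    for (t in shifted)
      for (i in seq_len(nrow(w)))
        if (t >= w[i, 1] && t < w[i, 2]) n <- n + 1L
    n / total
  }, numeric(1))
}

# independent sort-and-index percentile (linear interpolation between
# order statistics, matching quantile type 7)
oracle_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}
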