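#' Calcium transient ("spike") train of one cell
#'
#' @param cell_id Cell label.
#' @param event_times Event timestamps (s), sorted ascending.
#' @param threshold_used,baseline_mean,baseline_sd Detection provenance
#'   (fluorescence units); `NA` for trains not produced by [detect_spikes()].
#' @param peak_values Fluorescence at each detected peak (optional).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(cell_id, event_times, threshold_used = NA_real_,
                        baseline_mean = NA_real_, baseline_sd = NA_real_,
                        peak_values = NULL) {
  event_times <- as.numeric(event_times)
  if (is.unsorted(event_times)) event_times <- sort(event_times)
  structure(list(cell_id = as.character(cell_id),
                 event_times = event_times,
                 threshold_used = threshold_used,
                 baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 peak_values = peak_values),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike_train '%s': %d events", x$cell_id, length(x$event_times)))
  if (!is.na(x$threshold_used))
    cat(sprintf(" (threshold %.4g = %.4g + k x %.4g)", x$threshold_used,
                x$baseline_mean, x$baseline_sd))
  cat("\n")
  invisible(x)
}

#' Baseline mean and standard deviation of a fluorescence trace
#'
#' The detection threshold is `baseline_mean + multiplier * baseline_sd`.
#' `method = "full"` uses the whole trace (the simplest reading of a
#' whole-recording baseline); `method = "habituation"` restricts to the
#' pre-shock habituation segment, which excludes shock-evoked transients from
#' the baseline estimate. The sample (n-1) standard deviation is used. NaN
#' samples (dropped frames) are excluded.
#'
#' @param values Fluorescence series.
#' @param times Sample times (required for `method = "habituation"`).
#' @param method `"full"` or `"habituation"`.
#' @param habituation_end End of the habituation segment (s); default 300.
#' @return List with `mean` and `sd`.
#' @export
estimate_baseline <- function(values, times = NULL,
                              method = c("full", "habituation"),
                              habituation_end = 300) {
  method <- match.arg(method)
  v <- as.numeric(values)
  if (method == "habituation") {
    if (is.null(times)) stop("times required for the habituation baseline")
    v <- v[times < habituation_end]
  }
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("no finite samples to estimate a baseline from")
  s <- if (length(v) >= 2L) stats::sd(v) else 0
  list(mean = mean(v), sd = s)
}

#' Detect calcium transients by threshold crossing
#'
#' An event is a strict local maximum of the trace above
#' `baseline_mean + sd_multiplier * baseline_sd` (strict exceedance). A
#' contiguous supra-threshold excursion yields one event at the excursion's
#' maximum sample, so a single transient cannot produce multiple "spikes";
#' surviving events closer than `min_separation` are merged to the larger
#' peak. The event timestamp is the time of the peak sample.
#'
#' @param values Fluorescence series of one cell.
#' @param times Sample times (s).
#' @param baseline List with `mean` and `sd` (see [estimate_baseline()]).
#' @param sd_multiplier Threshold multiplier; default 2.
#' @param min_separation Minimum separation between events (s); default 0.25.
#' @param cell_id Cell label carried into the result.
#' @return A [spike_train()].
#' @export
detect_spikes <- function(values, times, baseline, sd_multiplier = 2,
                          min_separation = 0.25, cell_id = "cell") {
  v <- as.numeric(values)
  threshold <- baseline$mean + sd_multiplier * baseline$sd
  above <- !is.na(v) & v > threshold
  if (!any(above))
    return(spike_train(cell_id, numeric(0), threshold,
                       baseline$mean, baseline$sd, numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  peak_idx <- vapply(runs, function(k) {
    i <- starts[k]:ends[k]
    i[which.max(v[i])]
  }, integer(1))
  # merge peaks closer than min_separation, keeping the larger one
  if (length(peak_idx) > 1L) {
    repeat {
      tt <- times[peak_idx]
      gap <- diff(tt)
      close_pair <- which(gap < min_separation)
      if (length(close_pair) == 0L) break
      j <- close_pair[1L]
      drop <- if (v[peak_idx[j]] >= v[peak_idx[j + 1L]]) j + 1L else j
      peak_idx <- peak_idx[-drop]
    }
  }
  spike_train(cell_id, times[peak_idx], threshold, baseline$mean,
              baseline$sd, peak_values = v[peak_idx])
}

#' Detect transients for every cell of a trace matrix
#'
#' @param traces An aligned [trace_matrix()].
#' @param baseline_method Passed to [estimate_baseline()].
#' @param sd_multiplier,min_separation Passed to [detect_spikes()].
#' @return Named list of [spike_train()] objects, one per cell.
#' @export
detect_session <- function(traces, baseline_method = "full",
                           sd_multiplier = 2, min_separation = 0.25) {
  out <- lapply(seq_along(traces$cell_ids), function(j) {
    v <- traces$values[, j]
    b <- estimate_baseline(v, traces$times, method = baseline_method)
    detect_spikes(v, traces$times, b, sd_multiplier = sd_multiplier,
                  min_separation = min_separation,
                  cell_id = traces$cell_ids[j])
  })
  names(out) <- traces$cell_ids
  out
}
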