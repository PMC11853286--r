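#' Fluorescence trace matrix
#'
#' Time-aligned fluorescence series for all accepted cells of one session,
#' uniformly sampled (default 20 Hz).
#'
#' @param times Sample times in seconds, uniform grid.
#' @param values Numeric matrix, one column per cell (rows = time points).
#' @param cell_ids Unique cell labels; default taken from column names.
#' @param sampling_rate Hz; inferred from the median time step when `NULL`.
#' @param aligned Has the GPIO offset been applied (time 0 = experiment start)?
#' @return An object of class `trace_matrix`.
#' @export
trace_matrix <- function(times, values, cell_ids = colnames(values),
                         sampling_rate = NULL, aligned = FALSE) {
  values <- as.matrix(values)
  times <- as.numeric(times)
  if (length(times) != nrow(values))
    stop("length of times must equal number of rows of values")
  if (is.null(cell_ids)) cell_ids <- paste0("C", sprintf("%03d", seq_len(ncol(values))))
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  colnames(values) <- cell_ids
  if (length(times) >= 2L) {
    dt <- diff(times)
    med <- stats::median(dt)
    if (any(abs(dt - med) > 0.01 * med + 1e-9))
      stop("sample times are not uniform (>1% jitter)")
    if (is.null(sampling_rate)) sampling_rate <- 1 / med
    if (abs(1 / sampling_rate - med) > 1e-6)
      stop("sampling_rate inconsistent with time step")
  } else if (is.null(sampling_rate)) {
    stop("sampling_rate required for a single-sample trace")
  }
  structure(list(times = times, values = values, cell_ids = cell_ids,
                 sampling_rate = sampling_rate, aligned = isTRUE(aligned)),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("trace_matrix: %d cells x %d samples @ %g Hz (%s)\n",
              length(x$cell_ids), length(x$times), x$sampling_rate,
              if (x$aligned) "aligned" else "unaligned"))
  invisible(x)
}

#' GPIO synchronization record
#'
#' Timestamped values of hardware input channels on the acquisition clock;
#' the experiment-start trigger is recovered from the first rising event of
#' the trigger channel.
#'
#' @param channel Character vector of channel names, one per row.
#' @param timestamps Non-decreasing acquisition-clock times (s).
#' @param values Numeric channel values.
#' @return An object of class `gpio_record`.
#' @export
gpio_record <- function(channel, timestamps, values) {
  timestamps <- as.numeric(timestamps)
  if (is.unsorted(timestamps)) stop("GPIO timestamps must be non-decreasing")
  structure(list(channel = as.character(channel), timestamps = timestamps,
                 values = as.numeric(values)),
            class = "gpio_record")
}

# first time at which `trigger_channel` rises above `threshold`
gpio_trigger_time <- function(gpio, trigger_channel, threshold = 0.5) {
  sel <- gpio$channel == trigger_channel
  if (!any(sel)) stop(sprintf("no GPIO events on channel '%s'", trigger_channel))
  t <- gpio$timestamps[sel]
  v <- gpio$values[sel]
  hi <- which(v > threshold)
  if (length(hi) == 0L)
    stop(sprintf("no rising event on GPIO channel '%s'", trigger_channel))
  t[hi[1L]]
}

#' Align a trace matrix to the experiment start
#'
#' Subtracts the GPIO trigger time from all sample times so that time 0 is the
#' start of the behavioral protocol; samples recorded before the trigger (and,
#' when `session_length` is given, after the session end) are discarded.
#'
#' @param traces An unaligned [trace_matrix()].
#' @param gpio A [gpio_record()].
#' @param trigger_channel Channel carrying the experiment-start trigger.
#' @param session_length Optional session length (s); samples at or beyond it
#'   are dropped.
#' @return The aligned [trace_matrix()].
#' @export
align_to_experiment_start <- function(traces, gpio, trigger_channel = "GPIO-1",
                                      session_length = NULL) {
  if (isTRUE(traces$aligned)) stop("traces are already aligned")
  t0 <- gpio_trigger_time(gpio, trigger_channel)
  new_times <- traces$times - t0
  keep <- new_times >= 0
  if (!is.null(session_length)) keep <- keep & new_times < session_length
  if (!any(keep)) stop("GPIO trigger falls after the last trace sample: empty session")
  trace_matrix(new_times[keep], traces$values[keep, , drop = FALSE],
               cell_ids = traces$cell_ids, sampling_rate = traces$sampling_rate,
               aligned = TRUE)
}

#' Read / write a trace CSV
#'
#' A simplified IDPS-style export: a header row of `Time` plus one column per
#' cell, an optional second row with a per-cell accepted/rejected status (its
#' time field left blank), then one row per sample. Only cells marked
#' `accepted` are loaded; if the status row is absent all cells are loaded.
#'
#' @param path File path.
#' @param traces A [trace_matrix()] (for writing).
#' @param status Optional character vector of per-cell statuses to write.
#' @param aligned Whether the stored times are experiment-aligned.
#' @return `read_trace_csv` returns a [trace_matrix()].
#' @export
read_trace_csv <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stop(sprintf("trace file not found: %s", path))
  header <- strsplit(readLines(path, n = 2L), ",")[[1]]
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  cell_ids <- header[-1L]
  status <- NULL
  first_row <- raw[1L, , drop = FALSE]
  if (nrow(raw) > 0L && (is.na(suppressWarnings(as.numeric(first_row[[1L]]))) ||
                         first_row[[1L]] == "")) {
    status <- as.character(unlist(first_row[-1L]))
    raw <- raw[-1L, , drop = FALSE]
  }
  num <- as.matrix(vapply(raw, function(col) as.numeric(col),
                          numeric(nrow(raw))))
  times <- num[, 1L]
  if (any(is.na(times)) || is.unsorted(times, strictly = TRUE))
    stop("trace time column must be strictly increasing")
  values <- num[, -1L, drop = FALSE]
  if (!is.null(status)) {
    keep <- tolower(trimws(status)) != "rejected"
    values <- values[, keep, drop = FALSE]
    cell_ids <- cell_ids[keep]
  }
  trace_matrix(times, values, cell_ids = cell_ids, aligned = aligned)
}

#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(traces, path, status = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("Time", traces$cell_ids), collapse = ","), con)
  if (!is.null(status))
    writeLines(paste(c("", status), collapse = ","), con)
  body <- cbind(traces$times, traces$values)
  utils::write.table(
    matrix(formatC(body, format = "g", digits = 15), nrow = nrow(body)),
    con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a GPIO CSV
#'
#' Columns: `channel`, `time`, `value`.
#' @param path File path.
#' @param gpio A [gpio_record()] (for writing).
#' @return `read_gpio_csv` returns a [gpio_record()].
#' @export
read_gpio_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  gpio_record(d$channel, d$time, d$value)
}

#' @rdname read_gpio_csv
#' @export
write_gpio_csv <- function(gpio, path) {
  utils::write.csv(data.frame(channel = gpio$channel, time = gpio$timestamps,
                              value = gpio$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a behavioral event log
#'
#' BORIS-export-like CSV with columns `time`, `subject`, `behavior`,
#' `status` (`START`/`STOP`). Every `START` must have a later matching `STOP`
#' for the same behavior.
#'
#' @param path File path.
#' @param log A `behavior_log` data.frame (for writing).
#' @return `read_behavior_csv` returns a `behavior_log`: the event rows, with
#'   attribute `epochs` holding a data.frame of matched `(start, stop)` pairs
#'   per behavior.
#' @export
read_behavior_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  behavior_log(d)
}

#' @rdname read_behavior_csv
#' @export
write_behavior_csv <- function(log, path) {
  utils::write.csv(as.data.frame(log)[, c("time", "subject", "behavior", "status")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct and validate a behavioral event log
#'
#' @param events data.frame with columns `time`, `behavior`, `status`
#'   (`START`/`STOP`); an optional `subject` column is carried through.
#' @return The validated log (class `behavior_log`), with matched epochs in
#'   `attr(, "epochs")`.
#' @export
behavior_log <- function(events) {
  events <- as.data.frame(events)
  if (!all(c("time", "behavior", "status") %in% names(events)))
    stop("behavior log needs columns time, behavior, status")
  if (is.null(events$subject)) events$subject <- rep("observer", nrow(events))
  events$time <- as.numeric(events$time)
  if (nrow(events) > 0L && any(events$time < 0))
    stop("behavior event times must be non-negative")
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  epochs <- list()
  for (b in unique(events$behavior)) {
    sub <- events[events$behavior == b, , drop = FALSE]
    open <- NA_real_
    open_row <- NA_integer_
    for (i in seq_len(nrow(sub))) {
      st <- toupper(sub$status[i])
      if (st == "START") {
        if (!is.na(open))
          stop(sprintf("unmatched START for '%s' at t=%g (row %d)",
                       b, open, open_row))
        open <- sub$time[i]; open_row <- i
      } else if (st == "STOP") {
        if (is.na(open))
          stop(sprintf("STOP without START for '%s' at t=%g (row %d)",
                       b, sub$time[i], i))
        if (sub$time[i] <= open)
          stop(sprintf("STOP not after START for '%s' at t=%g (row %d)",
                       b, sub$time[i], i))
        epochs[[length(epochs) + 1L]] <-
          data.frame(behavior = b, start = open, stop = sub$time[i])
        open <- NA_real_
      } else stop(sprintf("unknown status '%s' (row %d)", sub$status[i], i))
    }
    if (!is.na(open))
      stop(sprintf("unmatched START for '%s' at t=%g (row %d)", b, open, open_row))
  }
  epochs <- if (length(epochs)) do.call(rbind, epochs) else
    data.frame(behavior = character(0), start = numeric(0), stop = numeric(0))
  epochs <- epochs[order(epochs$start), , drop = FALSE]
  rownames(epochs) <- NULL
  structure(events, epochs = epochs, class = c("behavior_log", "data.frame"))
}

#' Write a per-cell classification report
#'
#' TSV with one row per cell (`cell_id`, `n_spikes`, `off_rate`, `off_p95`,
#' `is_src`, `is_ssc`, `on_rate`, `on_p95`, `suppressed`, `on_only_src`) plus
#' a JSON session summary of the counts.
#'
#' @param reports List of `cell_report` objects (see [classify_cell()]).
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return The report data.frame, invisibly.
#' @export
write_report <- function(reports, tsv_path = NULL, json_path = NULL) {
  df <- report_table(reports)
  if (!is.null(tsv_path)) {
    out <- df
    for (col in c("off_rate", "off_p95", "on_rate", "on_p95"))
      out[[col]] <- formatC(out[[col]], format = "g", digits = 10)
    utils::write.table(out, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(session_summary(reports), json_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(df)
}

#' Tabulate cell reports
#' @param reports List of `cell_report` objects.
#' @return data.frame, one row per cell.
#' @export
report_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(cell_id = r$cell_id,
               n_spikes = r$n_spikes,
               off_rate = r$off_result$observed_rate,
               off_p95 = r$off_result$p95,
               is_src = r$is_src,
               is_ssc = r$is_ssc,
               on_rate = if (is.null(r$on_result)) NA_real_ else r$on_result$observed_rate,
               on_p95 = if (is.null(r$on_result)) NA_real_ else r$on_result$p95,
               suppressed = r$suppressed,
               on_only_src = r$on_only_src,
               stringsAsFactors = FALSE)
  }))
}
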