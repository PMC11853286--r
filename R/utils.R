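#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed: independent streams for per-cell / per-stage
# randomness, all derived from one master seed. Kept inside 32-bit range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483647L)
}

# Half-open membership t in [start, end)
in_window <- function(t, start, end) t >= start & t < end

# windows argument normalizer: accepts a 2-column matrix/data.frame or a
# list of length-2 vectors; returns a 2-column matrix (start, end).
as_windows <- function(windows) {
  if (is.null(windows) || length(windows) == 0L)
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  if (is.list(windows) && !is.data.frame(windows))
    windows <- do.call(rbind, lapply(windows, function(w) as.numeric(w[1:2])))
  w <- as.matrix(windows)
  if (ncol(w) != 2L) stop("windows must have two columns (start, end)")
  storage.mode(w) <- "double"
  if (any(w[, 2L] <= w[, 1L])) stop("every window must satisfy end > start")
  colnames(w) <- c("start", "end")
  w
}

pct1 <- function(n, total) round(100 * n / total, 1)

fmt_num <- function(x, digits = 6) formatC(x, format = "g", digits = digits)
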