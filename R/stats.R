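#' Two-sided chi-square goodness-of-fit test on two counts
#'
#' Pearson chi-square of observed counts against expected proportions,
#' without continuity correction (the convention that reproduces the
#' suppressed-SRC statistic of 23.148 on counts 26 vs 1 against a 50/50
#' split).
#'
#' @param observed Length-2 (or longer) vector of non-negative counts.
#' @param expected_proportions Expected proportions, same length; default
#'   uniform 50/50.
#' @return List of class `chisq_result`: `statistic`, `df`, `p`, `observed`,
#'   `expected`, `p_formatted`.
#' @export
chisq_goodness_of_fit <- function(observed, expected_proportions = NULL) {
  observed <- as.numeric(observed)
  if (any(observed < 0)) stop("counts must be non-negative")
  if (sum(observed) <= 0) stop("total count must be positive")
  if (is.null(expected_proportions))
    expected_proportions <- rep(1 / length(observed), length(observed))
  ct <- suppressWarnings(stats::chisq.test(observed, p = expected_proportions))
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p = ct$p.value,
                 observed = observed,
                 expected = unname(ct$expected),
                 p_formatted = format_p(ct$p.value)),
            class = "chisq_result")
}

#' Two-tailed paired t-test
#'
#' Standard paired t on the within-session differences; `df = n - 1`.
#' Identical pairs (zero-variance differences) make the statistic undefined
#' and are flagged rather than reported as a number.
#'
#' @param x,y Paired per-session values (equal length >= 2).
#' @return List of class `paired_t_result`: `t`, `df`, `p`, `p_formatted`,
#'   `mean_diff`, `undefined`.
#' @export
paired_t <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    return(structure(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                          p_formatted = NA_character_, mean_diff = mean(d),
                          undefined = TRUE),
                     class = "paired_t_result"))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, p_formatted = format_p(tt$p.value),
                 mean_diff = unname(tt$estimate), undefined = FALSE),
            class = "paired_t_result")
}

#' Format a p-value in reporting style
#'
#' Four decimals, with values below 0.0001 shown as `"< 0.0001"`.
#'
#' @param p Numeric p-value.
#' @return Character.
#' @export
format_p <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-4) "< 0.0001" else sprintf("%.4f", p)
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("chi-square GOF: X^2 = %.3f, df = %d, p %s\n",
              x$statistic, x$df,
              if (startsWith(x$p_formatted, "<")) x$p_formatted
              else paste("=", x$p_formatted)))
  invisible(x)
}

#' @export
print.paired_t_result <- function(x, ...) {
  if (isTRUE(x$undefined)) cat("paired t-test: undefined (zero-variance differences)\n")
  else cat(sprintf("paired t-test: t = %.4f, df = %d, p %s\n", x$t, x$df,
                   if (startsWith(x$p_formatted, "<")) x$p_formatted
                   else paste("=", x$p_formatted)))
  invisible(x)
}
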