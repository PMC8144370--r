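#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard error of the mean
#'
#' SEM of a numeric vector; a single observation has SEM 0 by convention
#' (no spread is observable).
#' @param x numeric vector
#' @return non-negative scalar
#' @keywords internal
sem <- function(x) {
  n <- length(x)
  if (n < 2L) return(0)
  stats::sd(x) / sqrt(n)
}

#' Kruskal-Wallis p-value with degenerate-input guard
#'
#' `stats::kruskal.test` produces NaN when every observation is tied (the tie
#' correction divides by zero); a constant gene carries no evidence of
#' zonation, so its p-value is 1.
#' @param values numeric vector of observations
#' @param groups group labels, same length
#' @return p-value in \[0, 1\]
#' @keywords internal
kw_pvalue <- function(values, groups) {
  if (length(unique(values)) < 2L) return(1)
  p <- suppressWarnings(stats::kruskal.test(values, as.factor(groups))$p.value)
  if (is.na(p)) 1 else p
}

#' Max-normalize rows of a matrix
#'
#' Divides each row by its maximum; all-zero rows stay zero.
#' @param m numeric matrix
#' @return matrix of same shape with row maxima 1 (or 0)
#' @keywords internal
max_normalize_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx[mx == 0] <- 1
  m / mx
}

#' Moving median with shrinking edge windows
#'
#' Centered running median of window `k`; near the boundaries the window
#' shrinks to the available points (no padding, no NA).
#' @param x numeric vector
#' @param k window size (default 10)
#' @return smoothed vector, same length
#' @export
moving_median <- function(x, k = 10L) {
  n <- length(x)
  if (n == 0L) return(x)
  lo <- floor((k - 1L) / 2L)
  hi <- ceiling((k - 1L) / 2L)
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1L, i - lo):min(n, i + hi)])
  }, numeric(1))
}

log_msg <- function(..., verbose = getOption("clumpseq.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[clumpseq] ", ...)
  invisible(NULL)
}
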