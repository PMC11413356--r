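#' Log-space p-value helpers
#'
#' GWAS p-values routinely reach magnitudes like 1e-32 and, on well-powered
#' traits, far beyond the smallest normalised double. All tail and quantile
#' computations in this package therefore run through [stats::pnorm()] /
#' [stats::qnorm()] with `log.p = TRUE`, and natural-log p-values are the
#' internal currency.
#'
#' @param z numeric vector of z-scores.
#' @return `log_p_from_z()` returns the natural log of the two-sided normal
#'   p-value; `p_from_z()` the p-value itself (which may underflow to 0 for
#'   |z| beyond ~38.6 -- keep the log form when that matters).
#' @keywords internal
#' @name log-pvalues
NULL

#' @rdname log-pvalues
log_p_from_z <- function(z) {
  log(2) + stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)
}

#' @rdname log-pvalues
p_from_z <- function(z) exp(log_p_from_z(z))

#' Two-sided normal quantile from a p-value, in log space
#'
#' Returns the |z| such that a two-sided normal test of that |z| gives the
#' supplied p-value. Accepts either `p` or its natural log so that
#' magnitudes like 1e-320 survive.
#'
#' @param p two-sided p-value in (0, 1); ignored when `log_p` is given.
#' @param log_p optional natural log of `p`.
#' @return the positive normal quantile |z|.
#' @keywords internal
z_from_p <- function(p = NULL, log_p = NULL) {
  if (is.null(log_p)) {
    stopifnot(is.numeric(p), all(p > 0), all(p < 1))
    log_p <- log(p)
  }
  stopifnot(all(log_p < 0))
  stats::qnorm(log_p - log(2), lower.tail = FALSE, log.p = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
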