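# Small shared helpers.

#' Inverse logit
#'
#' Numerically stable logistic function, mapping log-odds to probabilities.
#'
#' @param x Numeric vector of log-odds.
#' @return Probabilities in (0, 1).
#' @export
inv_logit <- function(x) stats::plogis(x)

#' Logit with clamping
#'
#' Log-odds of a proportion, after clamping to `[eps, 1 - eps]` so that
#' empirical proportions of 0 or 1 (common in small clusters) stay finite.
#'
#' @param p Numeric vector of proportions.
#' @param eps Clamping bound, default `1e-6`.
#' @return Log-odds.
#' @export
logit_clamped <- function(p, eps = 1e-6) {
  stats::qlogis(pmin(pmax(p, eps), 1 - eps))
}

# log P(y | eta) for y successes out of n trials under logit link,
# up to the binomial coefficient (constant in eta).
binom_loglik <- function(y, n, eta) {
  y * eta - n * log1p(exp(-abs(eta))) - n * pmax(eta, 0)
}

#' The three anthropometric-failure indicators
#'
#' Column-name stems used throughout the package for stunting
#' (height-for-age), underweight (weight-for-age) and wasting
#' (weight-for-height) prevalence.
#'
#' @return Character vector of indicator names.
#' @export
indicator_names <- function() c("stunting", "underweight", "wasting")

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}

# Effective sample size of an MCMC chain via the initial positive
# sequence of autocorrelations.
ess <- function(x) {
  n <- length(x)
  if (n < 10L || stats::sd(x) == 0) return(n)
  lag_max <- min(n - 1L, 200L)
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1L]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1L] - 1L)]
  n / (1 + 2 * sum(rho))
}
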