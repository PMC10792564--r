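#' Censored-normal (Tobit) log-density
#'
#' Log probability contribution of an observation from a normal latent
#' variable observed only within `[lo, hi]`: interior values contribute the
#' normal density, values at a bound contribute the probability mass beyond
#' that bound.  This is the per-observation likelihood used by the
#' trajectory model for every outcome component.
#'
#' @param y observed values on the modelling (log1p) scale, each in
#'   `[lo, hi]`.
#' @param mu latent means (recycled against `y`).
#' @param sigma latent standard deviation, a positive scalar.
#' @param lo,hi censoring bounds, `lo < hi`.
#' @return numeric vector of log-likelihood contributions.
#' @examples
#' censnorm_logpdf(0.5, mu = 0.5, sigma = 1, lo = 0, hi = 4) # log dnorm(0)
#' censnorm_logpdf(0,   mu = 0,   sigma = 1, lo = 0, hi = 4) # log 0.5
#' @export
censnorm_logpdf <- function(y, mu, sigma, lo, hi) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a positive scalar")
  if (lo >= hi) stop("'lo' must be strictly below 'hi'")
  n <- max(length(y), length(mu))
  y <- rep_len(y, n)
  mu <- rep_len(mu, n)
  if (any(y < lo - 1e-8 | y > hi + 1e-8, na.rm = TRUE))
    stop("observations outside the censoring bounds [lo, hi]")
  out <- stats::dnorm((y - mu) / sigma, log = TRUE) - log(sigma)
  at_lo <- y <= lo
  at_hi <- y >= hi
  if (any(at_lo))
    out[at_lo] <- stats::pnorm((lo - mu[at_lo]) / sigma, log.p = TRUE)
  if (any(at_hi))
    out[at_hi] <- stats::pnorm((hi - mu[at_hi]) / sigma, log.p = TRUE,
                               lower.tail = FALSE)
  out
}

## First and second derivatives of the censored-normal log-likelihood with
## respect to mu at fixed sigma, per observation.  Used by the Newton
## updates in the M-step.  Inverse Mills ratios are computed on the log
## scale for stability far into the tails.
censnorm_mu_derivs <- function(y, mu, sigma, lo, hi) {
  n <- length(y)
  g <- (y - mu) / sigma^2
  h <- rep.int(-1 / sigma^2, n)
  at_lo <- y <= lo
  at_hi <- y >= hi
  if (any(at_lo)) {
    z <- (lo - mu[at_lo]) / sigma
    lam <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
    g[at_lo] <- -lam / sigma
    h[at_lo] <- -lam * (lam + z) / sigma^2
  }
  if (any(at_hi)) {
    ## log(1 - Phi(z)) = log Phi(-z); derivatives mirror the left tail
    u <- (mu[at_hi] - hi) / sigma
    lam <- exp(stats::dnorm(u, log = TRUE) - stats::pnorm(u, log.p = TRUE))
    g[at_hi] <- lam / sigma
    h[at_hi] <- -lam * (lam + u) / sigma^2
  }
  list(g = g, h = h)
}
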