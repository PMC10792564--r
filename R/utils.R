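#' Row-wise log-sum-exp
#'
#' Numerically stable computation of `log(rowSums(exp(m)))`.
#'
#' @param m numeric matrix.
#' @return numeric vector with one entry per row of `m`.
#' @noRd
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

## Round-half-up, used for day -> month conversion.  base::round() rounds
## half to even, which would map a .5 tie downward half of the time.
round_half_up <- function(x) floor(x + 0.5)

## Mean Gregorian month length in days.
DAYS_PER_MONTH <- 30.4375

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(..., call. = FALSE)
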