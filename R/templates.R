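## Outcome metadata shared across the package.  Order is fixed:
## active joint count, physician global, parent global, ESR.
OUTCOMES <- c("ajc", "pga", "pge", "esr")
OUTCOME_MAX <- c(ajc = 71, pga = 100, pge = 100, esr = 200)

#' Censoring bounds on the log1p scale
#'
#' Lower bound 0 for every component; upper bounds at the instrument maxima
#' (71 active joints, 100 mm global assessment scales, 200 mm/h ESR).
#'
#' @return named list with elements `lo` and `hi`, each a named numeric
#'   vector over the four outcome components.
#' @export
outcome_bounds <- function() {
  list(lo = stats::setNames(rep(0, 4L), OUTCOMES), hi = log1p(OUTCOME_MAX))
}

CLUSTER_LEVELS <- c("fast_improver", "slow_improver", "improve_relapse",
                    "persistent_disease", "persistent_pga", "persistent_pge")

## Quadratic mean-trajectory anchors on the log1p scale: the mean value of
## each outcome at three months of follow-up.  The quadratic through the
## three anchors defines the template polynomial.  Anchors are calibrated so
## month-0 medians sit near typical UK registry baselines (around 5 active
## joints, 40 mm globals, 16-29 mm/h ESR) and so the six shapes reproduce
## the qualitative discovery patterns: parallel fast or slow improvement,
## improvement-then-relapse, globally persistent disease, and persistence of
## a single global assessment while everything else resolves.  ESR declines
## modestly and similarly in all clusters.
TEMPLATE_ANCHORS <- list(
  fast_improver = list(
    months = c(0, 3, 14),
    ajc = c(1.80, 0.25, 0.05), pga = c(3.70, 0.50, 0.10),
    pge = c(3.75, 0.50, 0.10), esr = c(3.00, 2.40, 2.20)),
  slow_improver = list(
    months = c(0, 6, 14),
    ajc = c(1.80, 1.10, 0.15), pga = c(3.70, 2.20, 0.30),
    pge = c(3.75, 2.30, 0.40), esr = c(3.00, 2.50, 2.20)),
  improve_relapse = list(
    months = c(0, 6, 14),
    ajc = c(1.80, 0.30, 1.60), pga = c(3.70, 0.80, 3.20),
    pge = c(3.75, 0.90, 3.30), esr = c(3.00, 2.40, 2.60)),
  persistent_disease = list(
    months = c(0, 6, 14),
    ajc = c(1.80, 1.70, 1.65), pga = c(3.70, 3.40, 3.30),
    pge = c(3.75, 3.50, 3.40), esr = c(3.00, 2.80, 2.75)),
  persistent_pga = list(
    months = c(0, 6, 14),
    ajc = c(1.80, 0.50, 0.08), pga = c(3.70, 3.30, 3.20),
    pge = c(3.75, 1.00, 0.15), esr = c(3.00, 2.40, 2.20)),
  persistent_pge = list(
    months = c(0, 6, 14),
    ajc = c(1.80, 0.50, 0.08), pga = c(3.70, 1.00, 0.15),
    pge = c(3.75, 3.45, 3.30), esr = c(3.00, 2.50, 2.30))
)

#' Default latent trajectory templates
#'
#' The six canonical response patterns after methotrexate initiation:
#' `fast_improver`, `slow_improver`, `improve_relapse`,
#' `persistent_disease`, `persistent_pga` and `persistent_pge`.  Each
#' template carries quadratic polynomial coefficients (intercept, linear,
#' quadratic in months since MTX start) for the mean of each JADAS71
#' component on the log1p scale.
#'
#' @return list of six objects of class `cluster_template`, each with
#'   elements `name` and `coef` (a 4 x 3 matrix, rows in the fixed outcome
#'   order ajc, pga, pge, esr).
#' @seealso [template_mean()], [synthetic_config()]
#' @export
default_templates <- function() {
  lapply(CLUSTER_LEVELS, function(nm) {
    a <- TEMPLATE_ANCHORS[[nm]]
    V <- outer(a$months, 0:2, `^`)
    coef <- t(vapply(OUTCOMES, function(o) solve(V, a[[o]]), numeric(3L)))
    dimnames(coef) <- list(OUTCOMES, c("b0", "b1", "b2"))
    structure(list(name = nm, coef = coef), class = "cluster_template")
  })
}

#' Evaluate a template's mean trajectories
#'
#' @param template a `cluster_template`.
#' @param months numeric vector of months since MTX start.
#' @param clamp clamp means into the censoring bounds (the latent mean used
#'   by the generator is unclamped; clamping is for display).
#' @return matrix of log1p-scale means, outcomes in rows, `months` in
#'   columns.
#' @export
template_mean <- function(template, months, clamp = FALSE) {
  V <- outer(months, 0:2, `^`)
  m <- template$coef %*% t(V)
  colnames(m) <- as.character(months)
  if (clamp) {
    b <- outcome_bounds()
    m <- pmin(pmax(m, b$lo[rownames(m)]), b$hi[rownames(m)])
  }
  m
}

#' @export
print.cluster_template <- function(x, ...) {
  cat("Trajectory template:", x$name, "\n")
  print(round(x$coef, 4))
  invisible(x)
}
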