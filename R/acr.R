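## The six JIA core outcome variables, as columns of a visit table.
CORE_VARS <- c("pga_mm", "pge_mm", "chaq", "ajc", "limited_joint_count",
               "esr")

#' Percent change between baseline and follow-up
#'
#' `100 * (followup - baseline) / baseline` for a positive baseline.  A
#' zero baseline with zero follow-up counts as no change; a zero baseline
#' with any positive follow-up counts as unbounded worsening (`Inf`), so it
#' always trips the 30%-worsening rule.
#'
#' @param baseline,followup non-negative values.
#' @return percent change (may be `Inf`).
#' @export
pct_change <- function(baseline, followup) {
  if (any(baseline < 0 | followup < 0, na.rm = TRUE))
    stop_config("core outcome variables must be non-negative")
  out <- 100 * (followup - baseline) / baseline
  zero_base <- !is.na(baseline) & baseline == 0
  out[zero_base & followup == 0] <- 0
  out[zero_base & followup > 0] <- Inf
  out
}

#' ACR Pediatric 30/90 composite response
#'
#' Response requires at least a 30% (or 90%) improvement in at least three
#' of the six JIA core outcome variables (physician global, parent global,
#' CHAQ, active joint count, limited joint count, ESR), with no more than
#' one variable worsening by more than 30%.
#'
#' @param baseline,followup named numeric vectors (or one-row data frames)
#'   containing the six core variables.
#' @param level 30 or 90, the required percent improvement.
#' @return `TRUE`/`FALSE`, or `NA` when either core set is incomplete (the
#'   child is not evaluable at this time point).
#' @examples
#' b <- c(pga_mm = 40, pge_mm = 40, chaq = 1, ajc = 4,
#'        limited_joint_count = 3, esr = 30)
#' acr_pedi(b, b * 0.5, level = 30)
#' @export
acr_pedi <- function(baseline, followup, level = 30) {
  stopifnot(level %in% c(30, 90))
  b <- unlist(baseline)[CORE_VARS]
  f <- unlist(followup)[CORE_VARS]
  if (anyNA(b) || anyNA(f)) return(NA)
  ch <- pct_change(b, f)
  sum(ch <= -level) >= 3L && sum(ch > 30) <= 1L
}

#' Select the assessment visit within a response window
#'
#' Among monthly assessments inside the window that carry a complete core
#' set, the one nearest the nominal month is chosen; ties go to the
#' earlier month.
#'
#' @param visits visit rows for one child with a `month` column and the six
#'   core variables.
#' @param window `"m6"` (months 4-8, nominal 6) or `"m12"` (months 10-14,
#'   nominal 12).
#' @return the selected row, or `NULL` when the window has no complete
#'   assessment.
#' @export
window_select <- function(visits, window = c("m6", "m12")) {
  window <- match.arg(window)
  lim <- if (window == "m6") c(4L, 8L, 6L) else c(10L, 14L, 12L)
  cand <- visits[visits$month >= lim[1L] & visits$month <= lim[2L], ,
                 drop = FALSE]
  cand <- cand[stats::complete.cases(cand[, CORE_VARS, drop = FALSE]), ,
               drop = FALSE]
  if (!nrow(cand)) return(NULL)
  d <- abs(cand$month - lim[3L])
  cand[order(d, cand$month)[1L], , drop = FALSE]
}

## Collapse a child's visits to one assessment row per month: core
## variables averaged component-wise across same-month visits.
.monthly_core <- function(visits) {
  if (!nrow(visits)) return(visits[, c("month", CORE_VARS), drop = FALSE])
  agg <- stats::aggregate(visits[, CORE_VARS, drop = FALSE],
                          by = list(month = visits$month),
                          FUN = function(v) {
                            v <- v[!is.na(v)]
                            if (length(v)) mean(v) else NA_real_
                          })
  agg[order(agg$month), , drop = FALSE]
}

#' Score ACR Pedi 30/90 for every child at 6 and 12 months
#'
#' Baseline is the month-0 assessment; the 6-month (months 4-8) and
#' 12-month (months 10-14) assessments are chosen by [window_select()].
#' Children lacking a complete six-variable core set at baseline or at the
#' window are flagged not evaluable (complete-case scoring; no
#' imputation).
#'
#' @param cohort preprocessed `mtx_cohort` (visits carry `month`).
#' @return data.frame with one row per child and window: per-variable
#'   percent changes, `pedi30`, `pedi90` and `evaluable`.
#' @export
score_acr <- function(cohort) {
  ids <- cohort$children$child_id
  rows <- list()
  for (id in ids) {
    vis <- .monthly_core(
      cohort$visits[cohort$visits$child_id == id, , drop = FALSE])
    base <- vis[vis$month == 0L, , drop = FALSE]
    base_ok <- nrow(base) == 1L &&
      !anyNA(base[, CORE_VARS, drop = FALSE])
    for (w in c("m6", "m12")) {
      fu <- window_select(vis, w)
      if (base_ok && !is.null(fu)) {
        ch <- pct_change(unlist(base[, CORE_VARS]), unlist(fu[, CORE_VARS]))
        p30 <- acr_pedi(base[, CORE_VARS], fu[, CORE_VARS], 30)
        p90 <- acr_pedi(base[, CORE_VARS], fu[, CORE_VARS], 90)
        rows[[length(rows) + 1L]] <- data.frame(
          child_id = id, window = w, month_used = fu$month,
          t(stats::setNames(ch, paste0("chg_", CORE_VARS))),
          pedi30 = p30, pedi90 = p90, evaluable = TRUE,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          child_id = id, window = w, month_used = NA_integer_,
          t(stats::setNames(rep(NA_real_, 6L),
                            paste0("chg_", CORE_VARS))),
          pedi30 = NA, pedi90 = NA, evaluable = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wilson score 95% confidence interval for a proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return numeric `c(lower, upper)`; `NA` when `n = 0`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(max(0, centre - half), min(1, centre + half))
}

#' ACR Pedi response proportions by trajectory cluster
#'
#' @param acr table from [score_acr()].
#' @param assignments named or ordered cluster labels per child: either a
#'   factor/character vector aligned with the unique children of `acr`, or
#'   a data.frame with `child_id` and `cluster`.
#' @return data.frame with one row per cluster x window x level:
#'   responders `k`, evaluable `n`, `proportion` and Wilson 95% CI.
#' @export
response_by_cluster <- function(acr, assignments) {
  if (is.data.frame(assignments)) {
    lab <- assignments$cluster[match(acr$child_id, assignments$child_id)]
  } else {
    ids <- unique(acr$child_id)
    lab <- assignments[match(acr$child_id, ids)]
  }
  lab <- as.character(lab)
  rows <- list()
  for (cl in unique(stats::na.omit(lab)))
    for (w in c("m6", "m12"))
      for (lev in c(30, 90)) {
        sel <- !is.na(lab) & lab == cl & acr$window == w & acr$evaluable
        resp <- if (lev == 30) acr$pedi30[sel] else acr$pedi90[sel]
        n <- sum(sel)
        k <- sum(resp)
        ci <- wilson_ci(k, n)
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = cl, window = w, level = lev, k = k, n = n,
          proportion = if (n) k / n else NA_real_,
          ci_lo = ci[1L], ci_hi = ci[2L], stringsAsFactors = FALSE)
      }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
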