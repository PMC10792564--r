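#' Convert day offsets to analysis months
#'
#' Follow-up time is analysed on a monthly grid: days since MTX start are
#' divided by the mean Gregorian month (30.4375 days) and rounded half-up,
#' then clamped at zero.
#'
#' @param day integer days from MTX initiation.
#' @return integer months.
#' @examples
#' day_to_month(c(0, 185, 426))
#' @export
day_to_month <- function(day) {
  pmax(as.integer(round_half_up(day / DAYS_PER_MONTH)), 0L)
}

#' Apply the pre-baseline window rule
#'
#' Visits more than three months (92 days) before MTX initiation are
#' dropped.  A visit within the three months before initiation is reset to
#' day zero, but only when the child has no visit on the exact initiation
#' date; if several pre-baseline visits qualify, the latest is kept and the
#' conflict recorded.
#'
#' @param visits visit table with `child_id` and `day` columns.
#' @return list with `visits` (rule applied) and `conflicts` (child ids
#'   where several pre-baseline visits competed for day zero).
#' @export
apply_baseline_window <- function(visits) {
  keep <- visits$day >= -92
  visits <- visits[keep, , drop = FALSE]
  pre <- visits$day < 0
  conflicts <- character(0)
  if (any(pre)) {
    for (id in unique(visits$child_id[pre])) {
      rows <- which(visits$child_id == id & visits$day < 0)
      has_day0 <- any(visits$child_id == id & visits$day == 0)
      if (has_day0) {
        visits$day[rows] <- NA_real_  # marked for dropping
      } else {
        latest <- rows[which.max(visits$day[rows])]
        if (length(rows) > 1L) conflicts <- c(conflicts, id)
        visits$day[setdiff(rows, latest)] <- NA_real_
        visits$day[latest] <- 0
      }
    }
    visits <- visits[!is.na(visits$day), , drop = FALSE]
  }
  rownames(visits) <- NULL
  list(visits = visits, conflicts = conflicts)
}

#' Censor visits after biologic initiation
#'
#' Outcome data collected after a child starts a biologic DMARD reflect the
#' new therapy, not methotrexate: visits strictly after the biologic start
#' day are removed.  Data collected on the day of initiation itself are
#' retained.
#'
#' @param cohort an `mtx_cohort` whose `children` table may carry
#'   `biologic_start_day`.
#' @return the cohort with censored visit rows removed.
#' @export
censor_at_biologic <- function(cohort) {
  ch <- cohort$children
  if (!"biologic_start_day" %in% names(ch)) return(cohort)
  if (any(ch$biologic_start_day < 0, na.rm = TRUE))
    stop_config("negative 'biologic_start_day' encountered")
  bio <- ch$biologic_start_day[match(cohort$visits$child_id, ch$child_id)]
  keep <- is.na(bio) | cohort$visits$day <= bio
  cohort$visits <- cohort$visits[keep, , drop = FALSE]
  rownames(cohort$visits) <- NULL
  cohort
}

#' JADAS10 composite disease activity score
#'
#' Active joints truncated at 10, plus the two global assessments on the
#' 0-10 cm scale (mm / 10), plus the ESR term `(esr - 20) / 10` clipped to
#' `[0, 10]`.  Range 0-40.
#'
#' @param ajc active joint count.
#' @param pga_mm,pge_mm physician / parent global assessments in mm.
#' @param esr erythrocyte sedimentation rate in mm/h.
#' @return numeric score; `NA` when any component is missing.
#' @examples
#' jadas10(2, 30, 20, 40) # 9
#' @export
jadas10 <- function(ajc, pga_mm, pge_mm, esr) {
  pmin(ajc, 10) + pga_mm / 10 + pge_mm / 10 +
    pmin(pmax((esr - 20) / 10, 0), 10)
}

## Baseline (month-0) visit per child: the earliest day-0..month-0 visit.
.baseline_rows <- function(visits) {
  m0 <- visits[visits$month == 0L, , drop = FALSE]
  m0 <- m0[order(m0$child_id, m0$day), , drop = FALSE]
  m0[!duplicated(m0$child_id), , drop = FALSE]
}

#' Eligibility filter
#'
#' Removes children who appear to be in clinically inactive disease at MTX
#' initiation (no active joints, or JADAS10 at or below the inactive-disease
#' cut-off of 1.0), and children who never have all four JADAS components
#' recorded simultaneously at a single visit.  When a children table carries
#' an `mtx_start_day` column, children with a missing MTX date are excluded
#' first; children who started a biologic within 30 days of MTX initiation
#' are excluded next (rapid intolerance or delayed MTX recording).  Each
#' child is attributed to the first matching rule.
#'
#' @param cohort preprocessed `mtx_cohort` (visits carry a `month` column).
#' @param cid_cutoff JADAS10 score at or below which disease is considered
#'   clinically inactive.
#' @return list with `cohort` (eligible children only) and `exclusions`, a
#'   named count per rule plus the retained count.
#' @export
eligibility_filter <- function(cohort, cid_cutoff = 1.0) {
  ch <- cohort$children
  vis <- cohort$visits
  n_in <- nrow(ch)
  rule <- rep(NA_character_, n_in)

  if ("mtx_start_day" %in% names(ch))
    rule[is.na(ch$mtx_start_day)] <- "no_mtx_date"
  if ("biologic_start_day" %in% names(ch)) {
    early_bio <- !is.na(ch$biologic_start_day) & ch$biologic_start_day <= 30
    rule[is.na(rule) & early_bio] <- "biologic_within_month"
  }

  base <- .baseline_rows(vis)
  idx <- match(ch$child_id, base$child_id)
  base_ajc <- base$ajc[idx]
  base_j10 <- jadas10(base$ajc, base$pga_mm, base$pge_mm, base$esr)[idx]
  cid <- (!is.na(base_ajc) & base_ajc == 0) |
    (!is.na(base_j10) & base_j10 <= cid_cutoff)
  rule[is.na(rule) & cid] <- "cid_at_baseline"

  complete <- stats::complete.cases(vis[, c("ajc", "pga_mm", "pge_mm",
                                            "esr")])
  has_complete <- ch$child_id %in% unique(vis$child_id[complete])
  rule[is.na(rule) & !has_complete] <- "no_complete_timepoint"

  keep <- is.na(rule)
  rules <- c("no_mtx_date", "biologic_within_month", "cid_at_baseline",
             "no_complete_timepoint")
  exclusions <- vapply(rules, function(r) sum(rule == r, na.rm = TRUE),
                       integer(1L))
  exclusions <- c(exclusions, retained = sum(keep))
  cohort$children <- ch[keep, , drop = FALSE]
  cohort$visits <- vis[vis$child_id %in% ch$child_id[keep], , drop = FALSE]
  rownames(cohort$children) <- rownames(cohort$visits) <- NULL
  list(cohort = cohort, exclusions = exclusions)
}

#' Long model frame on the log1p scale
#'
#' One row per (child, month, outcome) with `y = log1p(value)`.  Months
#' beyond 14 are dropped (follow-up is extended to 14 months to absorb late
#' one-year visits); duplicate observations of the same component in the
#' same month are collapsed by the mean of their log1p values.
#'
#' @param cohort eligible `mtx_cohort` with a `month` column on visits.
#' @return data.frame with columns `child_id`, `month`, `outcome`, `y`.
#' @export
to_model_frame <- function(cohort) {
  vis <- cohort$visits[cohort$visits$month <= 14L, , drop = FALSE]
  cols <- c(ajc = "ajc", pga = "pga_mm", pge = "pge_mm", esr = "esr")
  pieces <- lapply(names(cols), function(o) {
    v <- vis[[cols[[o]]]]
    ok <- !is.na(v)
    if (any(v[ok] < 0)) stop_config("negative outcome values in '", o, "'")
    data.frame(child_id = vis$child_id[ok], month = vis$month[ok],
               outcome = o, y = log1p(v[ok]), stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, pieces)
  agg <- stats::aggregate(y ~ child_id + month + outcome, data = long,
                          FUN = mean)
  agg$outcome <- factor(agg$outcome, levels = OUTCOMES)
  agg <- agg[order(agg$child_id, agg$month, agg$outcome), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Full preprocessing pipeline
#'
#' Applies, in order: the pre-baseline window rule, biologic censoring,
#' day-to-month conversion, the 14-month follow-up cap, the eligibility
#' filter, and the log1p model-frame transformation.  The pipeline is
#' idempotent: running it on its own output changes nothing.
#'
#' @param cohort raw `mtx_cohort` (days relative to MTX initiation).
#' @param cid_cutoff passed to [eligibility_filter()].
#' @return list with `cohort` (clean visits + eligible children),
#'   `model_frame`, `exclusions` and `conflicts`.
#' @export
preprocess_cohort <- function(cohort, cid_cutoff = 1.0) {
  bw <- apply_baseline_window(cohort$visits)
  cohort$visits <- bw$visits
  cohort <- censor_at_biologic(cohort)
  cohort$visits$month <- day_to_month(cohort$visits$day)
  cohort$visits <- cohort$visits[cohort$visits$month <= 14L, , drop = FALSE]
  rownames(cohort$visits) <- NULL
  ef <- eligibility_filter(cohort, cid_cutoff = cid_cutoff)
  list(cohort = ef$cohort, model_frame = to_model_frame(ef$cohort),
       exclusions = ef$exclusions, conflicts = bw$conflicts)
}
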