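#' Baseline covariate table for cluster characterization
#'
#' Joins the children table with month-0 values of the disease-activity
#' variables (component means across month-0 visits).
#'
#' @param cohort preprocessed `mtx_cohort`.
#' @return data.frame keyed by `child_id`.
#' @export
baseline_covariates <- function(cohort) {
  ch <- cohort$children
  base_cols <- c("ajc", "pga_mm", "pge_mm", "esr", "chaq",
                 "limited_joint_count")
  base_cols <- intersect(base_cols, names(cohort$visits))
  m0 <- cohort$visits[cohort$visits$month == 0L, , drop = FALSE]
  agg <- stats::aggregate(m0[, base_cols, drop = FALSE],
                          by = list(child_id = m0$child_id),
                          FUN = function(v) {
                            v <- v[!is.na(v)]
                            if (length(v)) mean(v) else NA_real_
                          })
  names(agg)[-1L] <- paste0("base_", base_cols)
  out <- merge(ch, agg, by = "child_id", all.x = TRUE, sort = TRUE)
  out[order(out$child_id), , drop = FALSE]
}

## Drop one of each collinear covariate pair (|r| > cutoff among numeric
## codings); the member with more available data is kept.
.collinearity_screen <- function(df, vars, cutoff = 0.8) {
  num <- lapply(df[vars], function(v)
    if (is.numeric(v)) v else as.numeric(factor(v)))
  num <- as.data.frame(num)
  drop <- character(0)
  if (length(vars) > 1L) {
    cm <- suppressWarnings(stats::cor(num, use = "pairwise.complete.obs"))
    cm[!is.finite(cm)] <- 0
    for (a in seq_len(ncol(cm) - 1L)) for (b in (a + 1L):ncol(cm)) {
      if (abs(cm[a, b]) > cutoff) {
        pair <- vars[c(a, b)]
        avail <- colSums(!is.na(num[pair]))
        drop <- union(drop, pair[which.min(avail)])
      }
    }
  }
  setdiff(vars, drop)
}

#' Multinomial logistic regression of cluster membership
#'
#' Maximum-likelihood multinomial logit of cluster labels on baseline
#' factors, against a reference cluster (by default the largest one, the
#' persistent-disease pattern).  `mode = "univariable"` fits one model per
#' covariate; `mode = "multivariable"` fits all non-collinear covariates
#' jointly.  Complete-case estimation; Wald 95% confidence intervals.
#'
#' @param covariates data.frame of per-child baseline factors (may include
#'   `child_id`, which is ignored as a predictor).
#' @param labels cluster labels aligned with the covariate rows.
#' @param reference reference cluster label; default the most frequent.
#' @param mode `"multivariable"` or `"univariable"`.
#' @param vars covariates to use; default all non-id columns.
#' @return object of class `mtx_multinom`: list of per-model coefficient
#'   tables (estimate, SE, OR, CI) plus fitted class probabilities for the
#'   multivariable model.
#' @export
fit_multinomial <- function(covariates, labels,
                            reference = NULL,
                            mode = c("multivariable", "univariable"),
                            vars = NULL) {
  mode <- match.arg(mode)
  labels <- as.character(labels)
  if (any(table(labels) == 0L)) stop_config("empty cluster label")
  if (is.null(reference))
    reference <- names(which.max(table(labels)))
  if (!reference %in% labels)
    stop_config("reference category '", reference, "' not present")
  y <- stats::relevel(factor(labels), ref = reference)
  vars <- vars %||% setdiff(names(covariates), "child_id")

  fit_one <- function(vs) {
    df <- data.frame(.y = y, covariates[vs], check.names = FALSE)
    df <- df[stats::complete.cases(df), , drop = FALSE]
    f <- stats::as.formula(paste(".y ~",
                                 paste(sprintf("`%s`", vs),
                                       collapse = " + ")))
    m <- nnet::multinom(f, data = df, trace = FALSE, maxit = 1000L,
                        abstol = 1e-12, reltol = 1e-13)
    co <- stats::coef(m)
    if (is.null(dim(co))) co <- matrix(co, nrow = 1L,
                                       dimnames = list(levels(y)[2L],
                                                       names(co)))
    se <- matrix(sqrt(diag(stats::vcov(m))), nrow = nrow(co),
                 byrow = TRUE, dimnames = dimnames(co))
    tab <- data.frame(
      cluster = rep(rownames(co), ncol(co)),
      term = rep(colnames(co), each = nrow(co)),
      estimate = as.vector(co), se = as.vector(se),
      stringsAsFactors = FALSE)
    tab$or <- exp(tab$estimate)
    tab$ci_lo <- exp(tab$estimate - 1.96 * tab$se)
    tab$ci_hi <- exp(tab$estimate + 1.96 * tab$se)
    tab$flagged <- abs(tab$estimate) > 10  # likely separation
    if (any(tab$flagged))
      warning("possible separation: some coefficients diverge")
    list(model = m, table = tab, n = nrow(df))
  }

  if (mode == "univariable") {
    models <- lapply(vars, function(v) fit_one(v))
    names(models) <- vars
    probs <- NULL
  } else {
    keep <- .collinearity_screen(covariates, vars)
    one <- fit_one(keep)
    models <- list(multivariable = one)
    probs <- stats::fitted(one$model)
    if (is.null(dim(probs)) || ncol(probs) == 1L)
      probs <- cbind(1 - as.vector(probs), as.vector(probs))
    colnames(probs) <- levels(y)
  }
  structure(list(mode = mode, reference = reference, models = models,
                 fitted_probs = probs),
            class = "mtx_multinom")
}

#' One-vs-rest AUC per cluster
#'
#' Area under the ROC curve of each cluster's predicted probability for
#' discriminating that cluster from all others, computed by the
#' rank-statistic (Mann-Whitney) formulation with mid-ranks for ties.
#'
#' @param probs matrix of class probabilities (columns named by cluster).
#' @param labels true cluster labels.
#' @return named numeric vector of AUCs; `NA` for clusters absent from
#'   `labels`.
#' @export
auc_one_vs_rest <- function(probs, labels) {
  labels <- as.character(labels)
  vapply(colnames(probs), function(cl) {
    pos <- labels == cl
    n1 <- sum(pos)
    n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    r <- rank(probs[, cl])
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1L))
}

#' Kaplan-Meier comparison of time to biologic therapy across clusters
#'
#' Product-limit survival estimates of MTX "survival" (time to biologic
#' addition or switch, in months, censored at 14) per trajectory cluster,
#' with a K-sample log-rank test.
#'
#' @param times follow-up times in months, in `(0, 14]`.
#' @param events 1 if a biologic was started at `times`, 0 if censored.
#' @param clusters cluster labels.
#' @return object of class `mtx_km`: per-cluster KM curve tables, event
#'   counts, and the log-rank chi-square statistic with its p-value
#'   (chi-square with K-1 degrees of freedom); the statistic is `NA` when
#'   no events occur.
#' @export
km_logrank <- function(times, events, clusters) {
  clusters <- factor(clusters)
  sf <- survival::survfit(survival::Surv(times, events) ~ clusters)
  ss <- summary(sf, censored = TRUE)
  strata <- if (is.null(ss$strata)) {
    rep(levels(clusters)[1L], length(ss$time))
  } else sub("^clusters=", "", as.character(ss$strata))
  curves <- split(data.frame(time = ss$time, n_risk = ss$n.risk,
                             n_event = ss$n.event, surv = ss$surv),
                  strata)
  n_event <- tapply(events, clusters, sum)
  if (sum(events) == 0L || nlevels(clusters) < 2L) {
    chisq <- NA_real_
    p <- NA_real_
  } else {
    sd <- survival::survdiff(survival::Surv(times, events) ~ clusters)
    chisq <- sd$chisq
    p <- stats::pchisq(chisq, df = nlevels(clusters) - 1L,
                       lower.tail = FALSE)
  }
  structure(list(curves = curves, n_event = n_event,
                 logrank_chisq = chisq, logrank_p = p),
            class = "mtx_km")
}

#' Time to biologic therapy from a cohort
#'
#' Months from MTX initiation to biologic start, censored at 14 months.
#'
#' @param cohort an `mtx_cohort` with `biologic_start_day` on `children`.
#' @return data.frame with `child_id`, `time` (months) and `event`.
#' @export
biologic_survival_data <- function(cohort) {
  ch <- cohort$children
  t_bio <- ch$biologic_start_day / DAYS_PER_MONTH
  event <- as.integer(!is.na(t_bio) & t_bio <= 14)
  time <- ifelse(event == 1L, pmax(t_bio, 0.01), 14)
  data.frame(child_id = ch$child_id, time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Descriptive summary of clusters at MTX initiation
#'
#' Per-cluster medians (IQR, linear-interpolation quantiles) for numeric
#' baseline variables and counts (%) for categorical ones, with
#' missingness percentages.
#'
#' @param covariates baseline covariate table (e.g.
#'   [baseline_covariates()]).
#' @param assignments cluster labels aligned with the rows.
#' @return data.frame in long form: cluster, variable, statistic, value.
#' @export
describe_clusters <- function(covariates, assignments) {
  lab <- as.character(assignments)
  vars <- setdiff(names(covariates), "child_id")
  rows <- list()
  for (cl in unique(lab)) {
    sub <- covariates[lab == cl, , drop = FALSE]
    for (v in vars) {
      x <- sub[[v]]
      miss <- 100 * mean(is.na(x))
      if (is.numeric(x)) {
        q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE,
                             names = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = cl, variable = v, n = sum(!is.na(x)),
          statistic = "median_iqr",
          value = sprintf("%.2f (%.2f, %.2f)", q[2L], q[1L], q[3L]),
          pct_missing = miss, stringsAsFactors = FALSE)
      } else {
        tab <- table(x)
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = cl, variable = v, n = sum(!is.na(x)),
          statistic = "counts",
          value = paste(sprintf("%s %d (%.0f%%)", names(tab), tab,
                                100 * tab / max(sum(tab), 1L)),
                        collapse = "; "),
          pct_missing = miss, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
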