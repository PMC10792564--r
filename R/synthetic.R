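#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the data-generating process: mixture weights over
#' the six latent trajectory templates, residual noise, the visit schedule,
#' missingness, per-cluster hazards of switching to a biologic DMARD, and a
#' simple baseline-covariate model.
#'
#' @param n_children number of children to simulate.
#' @param mixing mixture proportions over the six templates, in template
#'   order (fast improver, slow improver, improve-relapse, persistent
#'   disease, persistent PGA, persistent PGE).  Must sum to 1.
#' @param sigma per-outcome residual SD on the log1p scale (ajc, pga, pge,
#'   esr).
#' @param visit_days nominal follow-up schedule in days since MTX start.
#' @param visit_jitter_sd SD (days) of Gaussian jitter around the schedule.
#' @param p_missing_visit probability a non-baseline scheduled visit is
#'   skipped entirely.
#' @param p_missing_component per-component probability that a recorded
#'   visit lacks that JADAS component (recycled to length 4).
#' @param p_missing_extra per-variable missingness for the auxiliary core
#'   set variables (chaq, limited joint count, pain).
#' @param switch_hazard per-cluster monthly hazard of biologic initiation.
#' @param covariate_model list with elements `age_mean`, `age_sd`,
#'   `p_female`, `p_white`, `ilar_probs`, and optional per-cluster shifts
#'   `age_shift` (years) and `white_logodds_shift`.
#' @param missing_mechanism `"mcar"` (default) or `"mar"`; under `"mar"`
#'   the component-missingness log-odds increase with the current latent
#'   disease level by `mar_strength` per log1p unit.
#' @param mar_strength slope of the missing-at-random mechanism.
#' @param templates trajectory templates, defaults to [default_templates()].
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_children = 657,
                             mixing = c(fast_improver = 11,
                                        slow_improver = 16,
                                        improve_relapse = 7,
                                        persistent_disease = 44,
                                        persistent_pga = 8,
                                        persistent_pge = 13) / 99,
                             sigma = c(ajc = 0.55, pga = 0.70,
                                       pge = 0.70, esr = 0.65),
                             visit_days = c(0, 90, 180, 365),
                             visit_jitter_sd = 10,
                             p_missing_visit = 0.15,
                             p_missing_component = c(ajc = 0.05, pga = 0.15,
                                                     pge = 0.15, esr = 0.10),
                             p_missing_extra = c(chaq = 0.20,
                                                 limited_joint_count = 0.06,
                                                 pain_mm = 0.20),
                             switch_hazard = c(fast_improver = 0.0067,
                                               slow_improver = 0.0115,
                                               improve_relapse = 0.0203,
                                               persistent_disease = 0.0336,
                                               persistent_pga = 0.0158,
                                               persistent_pge = 0.0059),
                             covariate_model = list(
                               age_mean = 9, age_sd = 4,
                               p_female = 0.69, p_white = 0.84,
                               ilar_probs = c(systemic = 0.03,
                                              oligo_persistent = 0.18,
                                              oligo_extended = 0.18,
                                              rf_neg_poly = 0.33,
                                              rf_pos_poly = 0.10,
                                              era = 0.06,
                                              psoriatic = 0.08,
                                              undifferentiated = 0.04),
                               age_shift = c(fast_improver = -1.5,
                                             slow_improver = -2.0,
                                             improve_relapse = -1.5,
                                             persistent_disease = 0,
                                             persistent_pga = 0,
                                             persistent_pge = 0),
                               white_logodds_shift = c(fast_improver = 0,
                                                       slow_improver = 0,
                                                       improve_relapse = 0,
                                                       persistent_disease = 0,
                                                       persistent_pga = 0,
                                                       persistent_pge = -0.8)),
                             missing_mechanism = c("mcar", "mar"),
                             mar_strength = 0.3,
                             templates = default_templates(),
                             seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  K <- length(templates)
  if (!is.numeric(n_children) || n_children <= 0)
    stop_config("'n_children' must be a positive count")
  if (length(mixing) != K)
    stop_config("'mixing' must have one proportion per template")
  if (abs(sum(mixing) - 1) > 1e-9)
    stop_config("'mixing' must sum to 1 (got ", format(sum(mixing)), ")")
  if (any(mixing < 0)) stop_config("'mixing' proportions must be >= 0")
  if (n_children < K)
    stop_config("'n_children' must be at least the number of templates")
  probs <- c(p_missing_visit, p_missing_component, p_missing_extra,
             switch_hazard)
  if (any(probs < 0 | probs > 1))
    stop_config("all probabilities must lie in [0, 1]")
  if (any(sigma <= 0)) stop_config("'sigma' must be positive")
  ilar <- covariate_model$ilar_probs
  covariate_model$ilar_probs <- ilar / sum(ilar)
  structure(list(n_children = as.integer(n_children), mixing = mixing,
                 sigma = rep_len(sigma, 4L),
                 visit_days = visit_days, visit_jitter_sd = visit_jitter_sd,
                 p_missing_visit = p_missing_visit,
                 p_missing_component = rep_len(p_missing_component, 4L),
                 p_missing_extra = p_missing_extra,
                 switch_hazard = rep_len(switch_hazard, K),
                 covariate_model = covariate_model,
                 missing_mechanism = missing_mechanism,
                 mar_strength = mar_strength,
                 templates = templates, seed = as.integer(seed)),
            class = "synthetic_config")
}

## Native-scale rounding of a log1p-scale draw, clamped into [0, max].
.to_native <- function(y_log, o_max) {
  pmin(pmax(round(expm1(y_log)), 0), o_max)
}

#' Generate a synthetic MTX-response cohort
#'
#' Draws each child's latent cluster from the mixing proportions, simulates
#' jittered visit days around the nominal 0/3/6/12-month schedule, adds
#' censored-normal noise to the template mean trajectories on the log1p
#' scale, rounds back-transformed values to each instrument's native
#' resolution, and draws cluster-dependent biologic switch times from a
#' discrete monthly hazard.  Every child is guaranteed at least one visit
#' with all four JADAS components present (the analysis inclusion rule).
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_cohort`: a list with `children`
#'   (baseline table including `true_cluster`), `visits` (long visit
#'   table), and the `config` used.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_children = 50, seed = 7))
#' table(cohort$children$true_cluster)
#' @export
generate_cohort <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config"))
    stop_config("'config' must be created by synthetic_config()")
  set.seed(config$seed)
  n <- config$n_children
  K <- length(config$templates)
  tpl_names <- vapply(config$templates, `[[`, character(1L), "name")
  cm <- config$covariate_model
  bounds <- outcome_bounds()

  z <- sample.int(K, n, replace = TRUE, prob = config$mixing)

  age <- round(pmin(pmax(stats::rnorm(
    n, cm$age_mean + (cm$age_shift %||% rep(0, K))[z], cm$age_sd), 1), 16), 1)
  female <- stats::rbinom(n, 1L, cm$p_female)
  white <- stats::rbinom(n, 1L, stats::plogis(
    stats::qlogis(cm$p_white) + (cm$white_logodds_shift %||% rep(0, K))[z]))
  ilar <- sample(names(cm$ilar_probs), n, replace = TRUE,
                 prob = cm$ilar_probs)

  ## Biologic switch: geometric number of months until initiation under the
  ## per-cluster monthly hazard; switches beyond month 14 are never seen.
  switch_month <- stats::rgeom(n, pmax(config$switch_hazard[z], 1e-12)) + 1L
  switch_day <- ifelse(
    switch_month <= 14L,
    round((switch_month - stats::runif(n)) * DAYS_PER_MONTH), NA_real_)

  children <- data.frame(
    child_id = sprintf("C%04d", seq_len(n)),
    age_years = age,
    sex = ifelse(female == 1L, "female", "male"),
    ethnicity_white = white,
    ilar_category = ilar,
    biologic_start_day = switch_day,
    true_cluster = factor(tpl_names[z], levels = CLUSTER_LEVELS),
    stringsAsFactors = FALSE)

  nv <- length(config$visit_days)
  visit_rows <- vector("list", n)
  for (i in seq_len(n)) {
    days <- pmax(0, round(config$visit_days +
                            stats::rnorm(nv, 0, config$visit_jitter_sd)))
    days[1L] <- 0  # the baseline visit anchors day zero
    keep <- c(TRUE, stats::runif(nv - 1L) >= config$p_missing_visit)
    days <- sort(unique(days[keep]))
    months <- days / DAYS_PER_MONTH
    coef <- config$templates[[z[i]]]$coef
    V <- outer(months, 0:2, `^`)
    mu <- coef %*% t(V)  # 4 x n_visits latent means

    draw <- mu + stats::rnorm(length(mu), 0, config$sigma)
    draw <- pmin(pmax(draw, bounds$lo), bounds$hi)
    nat <- matrix(NA_real_, 4L, length(days),
                  dimnames = list(OUTCOMES, NULL))
    for (o in seq_len(4L))
      nat[o, ] <- .to_native(draw[o, ], OUTCOME_MAX[o])

    ## auxiliary core-set variables, derived from the same latent process
    lim_log <- pmax(0.9 * mu["ajc", ] + stats::rnorm(length(days), 0,
                                                     config$sigma[1L]), 0)
    limited <- pmin(pmax(round(expm1(pmin(lim_log, log1p(75)))), 0), 75)
    chaq_raw <- 0.30 * mu["pge", ] + stats::rnorm(length(days), 0, 0.25)
    chaq <- round(pmin(pmax(expm1(pmin(pmax(chaq_raw, 0), log1p(3))), 0), 3) /
                    0.125) * 0.125
    pain_log <- pmin(pmax(mu["pge", ] +
                            stats::rnorm(length(days), 0, config$sigma[3L]),
                          0), log1p(100))
    pain <- .to_native(pain_log, 100)

    ## component-level missingness (MCAR, or MAR on the latent level)
    pmc <- matrix(rep(config$p_missing_component, length(days)), 4L)
    if (config$missing_mechanism == "mar")
      pmc <- stats::plogis(stats::qlogis(pmc) +
                             config$mar_strength * (mu - 2))
    miss <- matrix(stats::runif(length(pmc)) < pmc, 4L)
    complete <- colSums(miss) == 0L
    if (!any(complete)) miss[, 1L] <- FALSE  # enforce inclusion rule
    nat[miss] <- NA_real_

    pme <- config$p_missing_extra
    chaq[stats::runif(length(days)) < pme[["chaq"]]] <- NA_real_
    limited[stats::runif(length(days)) < pme[["limited_joint_count"]]] <-
      NA_real_
    pain[stats::runif(length(days)) < pme[["pain_mm"]]] <- NA_real_

    visit_rows[[i]] <- data.frame(
      child_id = children$child_id[i], day = days,
      ajc = nat["ajc", ], pga_mm = nat["pga", ], pge_mm = nat["pge", ],
      esr = nat["esr", ], chaq = chaq, limited_joint_count = limited,
      pain_mm = pain, stringsAsFactors = FALSE)
  }
  visits <- do.call(rbind, visit_rows)
  rownames(visits) <- NULL

  structure(list(children = children, visits = visits, config = config),
            class = c("synthetic_cohort", "mtx_cohort"))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic MTX cohort:", nrow(x$children), "children,",
      nrow(x$visits), "visits (seed", x$config$seed, ")\n")
  print(table(x$children$true_cluster))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes `children.csv` and `visits.csv` (and, for synthetic cohorts,
#' `config.yaml` echoing the generator settings).
#'
#' @param cohort an `mtx_cohort`.
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(children = file.path(dir, "children.csv"),
             visits = file.path(dir, "visits.csv"))
  utils::write.csv(cohort$children, paths[["children"]], row.names = FALSE)
  utils::write.csv(cohort$visits, paths[["visits"]], row.names = FALSE)
  if (!is.null(cohort$config)) {
    cfg <- cohort$config
    echo <- cfg[setdiff(names(cfg), "templates")]
    echo$templates <- lapply(cfg$templates, function(t)
      list(name = t$name, coef = apply(t$coef, 1L, as.numeric,
                                       simplify = FALSE)))
    yaml::write_yaml(echo, file.path(dir, "config.yaml"))
    paths <- c(paths, config = file.path(dir, "config.yaml"))
  }
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `children.csv` and `visits.csv`.
#' @param mapping optional named character vector mapping this package's
#'   column names to the names used in the files (for external registries),
#'   e.g. `c(ajc = "active_joints")`.
#' @return an `mtx_cohort` list with `children` and `visits`.
#' @export
read_cohort <- function(dir, mapping = NULL) {
  for (f in c("children.csv", "visits.csv"))
    if (!file.exists(file.path(dir, f)))
      stop_config("required input file not found: ", file.path(dir, f))
  children <- utils::read.csv(file.path(dir, "children.csv"),
                              stringsAsFactors = FALSE)
  visits <- utils::read.csv(file.path(dir, "visits.csv"),
                            stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (std in names(mapping)) {
      for (tab in c("children", "visits")) {
        tb <- get(tab)
        hit <- match(mapping[[std]], names(tb))
        if (!is.na(hit)) {
          names(tb)[hit] <- std
          assign(tab, tb)
        }
      }
    }
  }
  need <- c("child_id", "day", "ajc", "pga_mm", "pge_mm", "esr")
  missing_cols <- setdiff(need, names(visits))
  if (length(missing_cols))
    stop_config("visits table lacks required columns: ",
                paste(missing_cols, collapse = ", "))
  if ("true_cluster" %in% names(children))
    children$true_cluster <- factor(children$true_cluster,
                                    levels = CLUSTER_LEVELS)
  structure(list(children = children, visits = visits),
            class = "mtx_cohort")
}
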