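#' Admissibility of a fitted trajectory model
#'
#' A fit is inadmissible when any trajectory group contains less than 1% of
#' the cohort, when any group's mean posterior probability of membership
#' among the children assigned to it (AvePP) falls below 70%, or when the
#' relative model entropy falls below 0.5.
#'
#' @param fit a `gbtm_fit`.
#' @param min_share,min_avepp,min_entropy admissibility thresholds.
#' @return list with `admissible` (flag) and `reasons` (character vector of
#'   failed rules, empty when admissible).
#' @export
admissible <- function(fit, min_share = 0.01, min_avepp = 0.70,
                       min_entropy = 0.5) {
  reasons <- character(0)
  if (any(fit$group_shares < min_share))
    reasons <- c(reasons, "min_share")
  if (any(is.na(fit$avepp)) || any(fit$avepp < min_avepp, na.rm = TRUE))
    reasons <- c(reasons, "min_avepp")
  if (fit$entropy < min_entropy)
    reasons <- c(reasons, "entropy")
  list(admissible = length(reasons) == 0L, reasons = reasons)
}

#' Fit the model-specification grid and select the optimal model
#'
#' Fits every combination of polynomial order and number of groups,
#' flags each fit for admissibility, and selects among the admissible fits
#' the one whose BIC is nearest zero (maximal under the penalised
#' log-likelihood convention).  The final "clinical relevance" choice in
#' the original workflow is a human decision: an explicit `override` can
#' force a different admissible grid entry, but is never applied
#' automatically.
#'
#' @param model_frame long model frame from [to_model_frame()].
#' @param orders polynomial orders to try.
#' @param K_range group counts to try.
#' @param n_starts,tol,max_iter,covariates,short_iter passed to
#'   [fit_gbtm()].
#' @param seed base seed; each grid cell derives its own sub-seed.
#' @param membership_covariates optional covariate names for the
#'   membership model (as in [gbtm_spec()]).
#' @param min_share,min_avepp,min_entropy admissibility thresholds.
#' @param override optional label `"P<order>_K<groups>"` naming the
#'   admissible entry to select instead of the BIC-optimal one.
#' @return object of class `gbtm_grid`: list with `grid` (one entry per
#'   fitted spec: fit, admissibility flag, reasons), `table` (summary data
#'   frame), `selected` (the chosen `gbtm_fit`) and the thresholds used.
#' @export
run_grid <- function(model_frame, orders = 1:3, K_range = 1:10,
                     n_starts = 8L, seed = 1L, tol = 1e-6,
                     max_iter = 500L, covariates = NULL,
                     membership_covariates = NULL,
                     min_share = 0.01, min_avepp = 0.70,
                     min_entropy = 0.5, override = NULL,
                     short_iter = 30L) {
  cells <- expand.grid(K = sort(unique(K_range)),
                       P = sort(unique(orders)))
  grid <- vector("list", nrow(cells))
  warm <- NULL
  for (i in seq_len(nrow(cells))) {
    P <- cells$P[i]
    K <- cells$K[i]
    spec <- gbtm_spec(K, P, membership_covariates = membership_covariates)
    ## ascending K within each order: the previous fit warm-starts the
    ## next via group-split starts
    if (!is.null(warm) &&
        (warm$spec$poly_order != P || warm$spec$n_groups != K - 1L))
      warm <- NULL
    fit <- fit_gbtm(model_frame, spec, n_starts = n_starts,
                    seed = seed + 1000L * P + 10L * K,
                    tol = tol, max_iter = max_iter,
                    covariates = covariates, warm = warm,
                    short_iter = short_iter)
    warm <- fit
    adm <- admissible(fit, min_share, min_avepp, min_entropy)
    grid[[i]] <- list(label = sprintf("P%d_K%d", P, K), fit = fit,
                      admissible = adm$admissible, reasons = adm$reasons)
  }
  tab <- do.call(rbind, lapply(grid, function(g) data.frame(
    label = g$label, poly_order = g$fit$spec$poly_order,
    n_groups = g$fit$spec$n_groups, loglik = g$fit$loglik,
    n_params = g$fit$n_params, bic = g$fit$bic, bic_obs = g$fit$bic_obs,
    entropy = g$fit$entropy, min_share = min(g$fit$group_shares),
    min_avepp = suppressWarnings(min(g$fit$avepp, na.rm = TRUE)),
    converged = g$fit$converged, admissible = g$admissible,
    reasons = paste(g$reasons, collapse = ";"),
    stringsAsFactors = FALSE)))

  ok <- which(tab$admissible)
  if (!length(ok)) {
    closest <- tab$label[which.max(tab$bic)]
    stop_config("no admissible model in the grid; closest candidate by ",
                "BIC is ", closest)
  }
  sel_idx <- ok[which.max(tab$bic[ok])]
  if (!is.null(override)) {
    oi <- match(override, tab$label)
    if (is.na(oi) || !tab$admissible[oi])
      stop_config("override '", override,
                  "' is not an admissible grid entry")
    sel_idx <- oi
  }
  structure(list(grid = grid, table = tab,
                 selected = grid[[sel_idx]]$fit,
                 selected_label = tab$label[sel_idx],
                 thresholds = c(min_share = min_share,
                                min_avepp = min_avepp,
                                min_entropy = min_entropy)),
            class = "gbtm_grid")
}

#' @export
print.gbtm_grid <- function(x, ...) {
  cat("GBTM specification grid (", nrow(x$table), " models), selected: ",
      x$selected_label, "\n", sep = "")
  print(x$table[, c("label", "loglik", "bic", "entropy", "min_share",
                    "min_avepp", "admissible", "reasons")],
        row.names = FALSE, digits = 5)
  invisible(x)
}

#' Write the selection report
#'
#' @param grid a `gbtm_grid`.
#' @param path JSON output path.
#' @return invisibly, `path`.
#' @export
write_selection_report <- function(grid, path) {
  out <- list(selected = grid$selected_label,
              thresholds = as.list(grid$thresholds),
              table = grid$table)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
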