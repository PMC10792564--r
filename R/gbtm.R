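#' Specify a multivariate group-based trajectory model
#'
#' @param n_groups number of latent trajectory groups, 1-10.
#' @param poly_order polynomial order of the mean trajectories in months
#'   (1 linear, 2 quadratic, 3 cubic).
#' @param outcomes outcome components (fixed order ajc, pga, pge, esr).
#' @param membership_covariates optional character vector naming per-child
#'   covariates (e.g. follow-up length) that enter the group-membership
#'   multinomial model.
#' @return object of class `gbtm_spec`.
#' @export
gbtm_spec <- function(n_groups, poly_order = 2L, outcomes = OUTCOMES,
                      membership_covariates = NULL) {
  if (!n_groups %in% 1:10)
    stop_config("'n_groups' must be an integer in 1..10")
  if (!poly_order %in% 1:3)
    stop_config("'poly_order' must be 1, 2 or 3")
  b <- outcome_bounds()
  structure(list(n_groups = as.integer(n_groups),
                 poly_order = as.integer(poly_order),
                 outcomes = outcomes,
                 lo = b$lo[outcomes], hi = b$hi[outcomes],
                 membership_covariates = membership_covariates),
            class = "gbtm_spec")
}

## Internal observation layout: observations split by outcome with
## child indices, polynomial design matrices and censoring bounds.
.gbtm_data <- function(model_frame, spec, covariates = NULL) {
  children <- sort(unique(model_frame$child_id))
  n <- length(children)
  oi <- match(as.character(model_frame$outcome), spec$outcomes)
  if (anyNA(oi)) stop_config("model frame contains unknown outcomes")
  per_outcome <- lapply(seq_along(spec$outcomes), function(o) {
    sel <- which(oi == o)
    t <- model_frame$month[sel]
    list(y = model_frame$y[sel],
         child = match(model_frame$child_id[sel], children),
         X = outer(t, 0:spec$poly_order, `^`),
         lo = spec$lo[[o]], hi = spec$hi[[o]])
  })
  Xm <- NULL
  if (!is.null(spec$membership_covariates)) {
    if (is.null(covariates))
      stop_config("spec requests membership covariates but none supplied")
    idx <- match(children, covariates$child_id)
    if (anyNA(idx))
      stop_config("membership covariates missing for some children")
    Xm <- cbind(1, as.matrix(
      covariates[idx, spec$membership_covariates, drop = FALSE]))
    dimnames(Xm) <- NULL
  }
  list(children = children, n = n, per_outcome = per_outcome, Xm = Xm,
       n_obs = nrow(model_frame))
}

## Per-child log-likelihood matrix (n x K) given trajectory parameters.
.gbtm_llmat <- function(dat, beta, sigma) {
  K <- dim(beta)[1L]
  ll <- matrix(0, dat$n, K)
  for (o in seq_along(dat$per_outcome)) {
    po <- dat$per_outcome[[o]]
    if (!length(po$y)) next
    for (k in seq_len(K)) {
      mu <- drop(po$X %*% beta[k, o, ])
      lp <- censnorm_logpdf(po$y, mu, sigma[o], po$lo, po$hi)
      acc <- rowsum(lp, po$child)
      ll[as.integer(rownames(acc)), k] <-
        ll[as.integer(rownames(acc)), k] + acc
    }
  }
  ll
}

## log membership probabilities, n x K: either log pi (no covariates) or
## the multinomial-logit probabilities from gamma.
.gbtm_logpi <- function(dat, pi, gamma) {
  if (is.null(dat$Xm)) {
    matrix(log(pmax(pi, 1e-300)), dat$n, length(pi), byrow = TRUE)
  } else {
    eta <- dat$Xm %*% t(gamma)
    eta - row_logsumexp(eta)
  }
}

#' Observed-data log-likelihood of a censored-normal GBTM
#'
#' Sum over children of the log mixture density, where each group's
#' contribution is the product of censored-normal densities over the
#' child's observed (outcome, month) pairs.
#'
#' @param model_frame long model frame from [to_model_frame()].
#' @param spec a [gbtm_spec()].
#' @param beta coefficient array `K x n_outcomes x (poly_order + 1)`.
#' @param sigma per-outcome residual SDs.
#' @param pi mixing proportions (length K).
#' @param gamma optional multinomial membership coefficients
#'   (`K x (1 + n_covariates)`, first row zero) used instead of `pi` when
#'   the spec has membership covariates.
#' @param covariates per-child covariate table when `gamma` is used.
#' @return scalar log-likelihood.
#' @export
gbtm_loglik <- function(model_frame, spec, beta, sigma, pi, gamma = NULL,
                        covariates = NULL) {
  if (!all(is.finite(beta)) || !all(is.finite(sigma)))
    stop_config("non-finite parameters")
  dat <- .gbtm_data(model_frame, spec, covariates)
  ll <- .gbtm_llmat(dat, beta, sigma)
  sum(row_logsumexp(ll + .gbtm_logpi(dat, pi, gamma)))
}

#' Relative entropy of a posterior classification
#'
#' `1 - H / (n log K)` where `H` is the total Shannon entropy of the
#' posterior membership probabilities; 1 means perfectly sharp assignment,
#' 0 maximal uncertainty.  Defined as 1 when `K = 1`.
#'
#' @param posterior `n x K` posterior matrix, rows summing to 1.
#' @param K number of groups.
#' @return value in `[0, 1]`.
#' @export
relative_entropy <- function(posterior, K = ncol(posterior)) {
  if (K <= 1L) return(1)
  p <- pmax(posterior, 0)
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  1 - h / (nrow(posterior) * log(K))
}

#' BIC under the sign convention where values nearer zero are better
#'
#' `loglik - n_params/2 * log(n)`; the penalised log-likelihood form used
#' in the trajectory-modelling literature (typically negative, maximised).
#'
#' @param loglik maximised log-likelihood.
#' @param n_params number of free parameters.
#' @param n number of independent units (children).
#' @return scalar BIC.
#' @export
gbtm_bic <- function(loglik, n_params, n) {
  loglik - 0.5 * n_params * log(n)
}

#' Number of free parameters of a GBTM
#'
#' `(K - 1)` mixing parameters (times `1 + q` when `q` membership
#' covariates are present), `K * n_outcomes * (P + 1)` trajectory
#' coefficients, and one residual SD per outcome.
#'
#' @param spec a [gbtm_spec()].
#' @return integer count.
#' @export
gbtm_n_params <- function(spec) {
  K <- spec$n_groups
  q <- length(spec$membership_covariates)
  no <- length(spec$outcomes)
  as.integer((K - 1L) * (1L + q) + K * no * (spec$poly_order + 1L) + no)
}

## ---- M-step helpers --------------------------------------------------

## Guarded Newton update of one group's trajectory coefficients for one
## outcome at fixed sigma.  The censored-normal log-likelihood is concave
## in beta, so the Newton direction ascends; step-halving protects against
## overshoot so the generalized-EM ascent property holds exactly.
.update_beta <- function(po, beta_ko, w, sigma) {
  qfun <- function(b) {
    mu <- drop(po$X %*% b)
    sum(w * censnorm_logpdf(po$y, mu, sigma, po$lo, po$hi))
  }
  q0 <- qfun(beta_ko)
  for (it in 1:2) {
    mu <- drop(po$X %*% beta_ko)
    d <- censnorm_mu_derivs(po$y, mu, sigma, po$lo, po$hi)
    gr <- crossprod(po$X, w * d$g)
    H <- crossprod(po$X, (w * d$h) * po$X)
    step <- tryCatch(solve(H, gr), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    ok <- FALSE
    fac <- 1
    for (half in 1:8) {
      cand <- beta_ko - fac * drop(step)
      qc <- qfun(cand)
      if (is.finite(qc) && qc >= q0 - 1e-12) {
        beta_ko <- cand
        q0 <- qc
        ok <- TRUE
        break
      }
      fac <- fac / 2
    }
    if (!ok) break
  }
  beta_ko
}

## Pooled residual-SD update for one outcome: golden-section search of the
## weighted Q over sigma, never accepting a decrease.  `W` holds the
## posterior weights already expanded to observation level (rows of `po`).
.update_sigma <- function(po, beta_o, W, sigma0) {
  K <- ncol(W)
  yrep <- rep(po$y, K)
  murep <- as.vector(po$X %*% t(beta_o))
  wrep <- as.vector(W)
  qfun <- function(s) sum(wrep * censnorm_logpdf(yrep, murep, s,
                                                 po$lo, po$hi))
  opt <- stats::optimize(function(ls) qfun(exp(ls)),
                         interval = log(sigma0) + c(-0.5, 0.5),
                         maximum = TRUE, tol = 2e-3)
  if (opt$objective > qfun(sigma0)) max(exp(opt$maximum), 0.02) else sigma0
}

## One guarded Newton step on the membership multinomial coefficients.
.update_gamma <- function(Xm, post, gamma) {
  K <- ncol(post)
  if (K < 2L) return(gamma)
  q <- ncol(Xm)
  qfun <- function(g) {
    eta <- Xm %*% t(g)
    lp <- eta - row_logsumexp(eta)
    sum(post * lp)
  }
  q0 <- qfun(gamma)
  eta <- Xm %*% t(gamma)
  Pi <- exp(eta - row_logsumexp(eta))
  free <- 2:K
  gr <- as.vector(vapply(free, function(k)
    crossprod(Xm, post[, k] - Pi[, k]), numeric(q)))
  H <- matrix(0, (K - 1L) * q, (K - 1L) * q)
  for (a in seq_along(free)) for (b in seq_along(free)) {
    k <- free[a]; l <- free[b]
    wkl <- Pi[, k] * ((k == l) - Pi[, l])
    H[(a - 1L) * q + 1:q, (b - 1L) * q + 1:q] <- -crossprod(Xm, wkl * Xm)
  }
  step <- tryCatch(solve(H, gr), error = function(e) NULL)
  if (is.null(step) || !all(is.finite(step))) return(gamma)
  fac <- 1
  for (half in 1:8) {
    cand <- gamma
    cand[free, ] <- gamma[free, ] -
      fac * matrix(step, K - 1L, q, byrow = TRUE)
    if (qfun(cand) >= q0 - 1e-12) return(cand)
    fac <- fac / 2
  }
  gamma
}

## ---- initialisation --------------------------------------------------

## Per-child profile features for k-means starts: each outcome's mean y
## within the nominal follow-up bins (baseline, ~3, ~6, ~12 months), with
## missing cells filled by the child's outcome mean (or the grand mean),
## so the features trace trajectory shape rather than just level.
.start_features <- function(dat) {
  n <- dat$n
  bins <- list(c(0, 1), c(2, 4), c(5, 8), c(9, 14))
  feats <- matrix(NA_real_, n, 4L * length(dat$per_outcome))
  for (o in seq_along(dat$per_outcome)) {
    po <- dat$per_outcome[[o]]
    t <- po$X[, 2L]
    child_mean <- rep(NA_real_, n)
    mn <- tapply(po$y, po$child, mean)
    child_mean[as.integer(names(mn))] <- mn
    for (b in seq_along(bins)) {
      sel <- t >= bins[[b]][1L] & t <= bins[[b]][2L]
      col <- (o - 1L) * 4L + b
      if (any(sel)) {
        cm <- tapply(po$y[sel], po$child[sel], mean)
        feats[as.integer(names(cm)), col] <- cm
      }
      fill <- is.na(feats[, col])
      feats[fill, col] <- child_mean[fill]
    }
  }
  feats[is.na(feats)] <- 0
  grand <- colMeans(feats)
  sds <- apply(feats, 2L, stats::sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  scale(feats, center = grand, scale = sds)
}

## Parameters from a hard partition: per-group weighted least squares on
## the (uncensored) log1p values, pooled residual SD per outcome.
.init_from_partition <- function(dat, part, spec) {
  K <- spec$n_groups
  P1 <- spec$poly_order + 1L
  no <- length(dat$per_outcome)
  beta <- array(0, c(K, no, P1))
  sigma <- numeric(no)
  for (o in seq_len(no)) {
    po <- dat$per_outcome[[o]]
    g_obs <- part[po$child]
    XtX_all <- crossprod(po$X)
    b_all <- solve(XtX_all + diag(1e-8, P1), crossprod(po$X, po$y))
    res2 <- 0
    for (k in seq_len(K)) {
      sel <- g_obs == k
      if (sum(sel) >= P1 + 1L) {
        Xk <- po$X[sel, , drop = FALSE]
        bk <- tryCatch(
          solve(crossprod(Xk) + diag(1e-8, P1), crossprod(Xk, po$y[sel])),
          error = function(e) b_all)
      } else bk <- b_all
      beta[k, o, ] <- bk
      if (any(sel))
        res2 <- res2 + sum((po$y[sel] - po$X[sel, , drop = FALSE] %*%
                              beta[k, o, ])^2)
    }
    sigma[o] <- if (length(po$y)) max(sqrt(res2 / length(po$y)), 0.1)
                else 1
  }
  pi <- tabulate(part, K) / length(part)
  pi <- pmax(pi, 1e-3)
  list(beta = beta, sigma = sigma, pi = pi / sum(pi))
}

## ---- EM driver -------------------------------------------------------

.run_em <- function(dat, spec, init, tol, max_iter) {
  K <- spec$n_groups
  beta <- init$beta
  sigma <- init$sigma
  pi <- init$pi
  gamma <- init$gamma
  if (is.null(gamma) && !is.null(dat$Xm)) {
    gamma <- matrix(0, K, ncol(dat$Xm))
    gamma[, 1L] <- log(pmax(pi, 1e-6)) - log(pi[1L])
  }
  ll <- ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  post <- NULL
  for (iter in seq_len(max_iter)) {
    llmat <- .gbtm_llmat(dat, beta, sigma) + .gbtm_logpi(dat, pi, gamma)
    lse <- row_logsumexp(llmat)
    ll <- sum(lse)
    trace <- c(trace, ll)
    post <- exp(llmat - lse)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 0.1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    ## M-step
    if (is.null(dat$Xm)) {
      pi <- pmax(colMeans(post), 1e-12)
      pi <- pi / sum(pi)
    } else {
      gamma <- .update_gamma(dat$Xm, post, gamma)
    }
    for (o in seq_along(dat$per_outcome)) {
      po <- dat$per_outcome[[o]]
      if (!length(po$y)) next
      W <- post[po$child, , drop = FALSE]
      for (k in seq_len(K)) {
        if (sum(W[, k]) < spec$poly_order + 2L) next  # degenerate group
        beta[k, o, ] <- .update_beta(po, beta[k, o, ], W[, k], sigma[o])
      }
      beta_o <- matrix(beta[, o, , drop = FALSE], nrow = K)
      sigma[o] <- .update_sigma(po, beta_o, W, sigma[o])
    }
  }
  list(beta = beta, sigma = sigma, pi = pi, gamma = gamma,
       loglik = ll, trace = trace, post = post, converged = converged)
}

#' Fit a multivariate censored-normal GBTM by multi-start EM
#'
#' The E-step computes posterior group memberships by log-sum-exp; the
#' M-step updates mixing proportions (or the membership multinomial when
#' covariates are present), performs guarded Newton updates of each
#' group-by-outcome Tobit polynomial regression, and refreshes the pooled
#' per-outcome residual SDs.  Starting values come from k-means on
#' per-child summary features, plus perturbed restarts; each start is run
#' for a short burn-in and the best is polished to convergence.  Groups are
#' relabelled in decreasing share order before return.
#'
#' @param model_frame long model frame from [to_model_frame()].
#' @param spec a [gbtm_spec()].
#' @param n_starts number of EM starts.
#' @param seed integer seed controlling starts (fits are deterministic
#'   given `seed` and `n_starts`).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations for the polishing run.
#' @param covariates per-child covariate table (needed when the spec has
#'   membership covariates).
#' @param short_iter burn-in EM iterations per start.
#' @param warm optional `gbtm_fit` with `K - 1` groups whose assignment
#'   seeds additional group-split starts; when absent (and `K > 1`) the
#'   fitter builds the ladder of smaller models itself.
#' @return object of class `gbtm_fit`; see Details.
#' @details The fit carries mixing proportions `pi` (or membership
#'   coefficients `gamma`), the coefficient array `beta`
#'   (`K x outcome x power`), per-outcome `sigma`, the observed-data
#'   `loglik` and its EM `loglik_trace`, `bic` (children as the independent
#'   units) and `bic_obs` (total observations), the posterior matrix,
#'   modal `assignment`, `group_shares`, per-group mean posterior
#'   probability `avepp`, relative `entropy`, and convergence flags.
#' @export
fit_gbtm <- function(model_frame, spec, n_starts = 8L, seed = 1L,
                     tol = 1e-6, max_iter = 500L, covariates = NULL,
                     short_iter = 30L, warm = NULL) {
  K <- spec$n_groups
  if (!is.null(warm) &&
      (!inherits(warm, "gbtm_fit") || warm$spec$n_groups != K - 1L))
    warm <- NULL
  if (K > 1L && is.null(warm)) {
    ## stepwise build-up: reach K by splitting groups of the best K-1
    ## solution, the standard remedy for local optima in trajectory models
    for (k in seq_len(K - 1L)) {
      wspec <- gbtm_spec(k, spec$poly_order, spec$outcomes,
                         spec$membership_covariates)
      warm <- .fit_gbtm_one(model_frame, wspec, n_starts,
                            seed = seed + k, tol = tol,
                            max_iter = max_iter, covariates = covariates,
                            short_iter = short_iter, warm = warm)
    }
  }
  .fit_gbtm_one(model_frame, spec, n_starts, seed, tol, max_iter,
                covariates, short_iter, warm)
}

.fit_gbtm_one <- function(model_frame, spec, n_starts, seed, tol,
                          max_iter, covariates, short_iter, warm) {
  dat <- .gbtm_data(model_frame, spec, covariates)
  K <- spec$n_groups
  if (dat$n < K)
    stop_config("need at least as many children as groups")
  set.seed(seed)

  parts <- vector("list", n_starts)
  if (K == 1L) {
    parts <- rep(list(rep(1L, dat$n)), 1L)  # one start suffices
  } else {
    feats <- .start_features(dat)
    kmpart <- function(nstart) {
      km <- tryCatch(
        stats::kmeans(feats, centers = K, nstart = nstart,
                      iter.max = 50L),
        error = function(e) NULL)
      if (is.null(km)) sample.int(K, dat$n, TRUE) else km$cluster
    }
    parts[[1L]] <- kmpart(10L)
    for (s in seq_len(n_starts - 1L) + 1L) {
      p <- if (s %% 2L == 0L) {
        kmpart(1L)  # fresh k-means from random centres
      } else {
        p0 <- parts[[1L]]  # perturbed best k-means partition
        flip <- stats::runif(dat$n) < 0.3
        p0[flip] <- sample.int(K, sum(flip), replace = TRUE)
        p0
      }
      ## make sure every group is represented
      missing_g <- setdiff(seq_len(K), unique(p))
      if (length(missing_g))
        p[sample.int(dat$n, length(missing_g))] <- missing_g
      parts[[s]] <- p
    }
    if (!is.null(warm)) {
      ## split starts: take the K-1 assignment and split each group in
      ## two by k-means on the child features
      asg <- warm$assignment[match(dat$children, warm$children)]
      if (!anyNA(asg)) {
        for (g in seq_len(K - 1L)) {
          sel <- which(asg == g)
          if (length(sel) < 2L * (spec$poly_order + 2L)) next
          km2 <- tryCatch(
            stats::kmeans(feats[sel, , drop = FALSE], 2L, nstart = 5L),
            error = function(e) NULL)
          if (is.null(km2)) next
          p <- asg
          p[sel[km2$cluster == 2L]] <- K
          if (length(unique(p)) == K)
            parts[[length(parts) + 1L]] <- p
        }
      }
    }
  }

  short <- lapply(parts, function(p) {
    init <- .init_from_partition(dat, p, spec)
    .run_em(dat, spec, init, tol = 1e-4, max_iter = short_iter)
  })
  ## polish the two most promising burn-in runs to convergence
  ranks <- order(vapply(short, `[[`, numeric(1L), "loglik"),
                 decreasing = TRUE)
  finals <- lapply(ranks[seq_len(min(2L, length(ranks)))], function(b)
    .run_em(dat, spec, short[[b]], tol = tol, max_iter = max_iter))
  em <- finals[[which.max(vapply(finals, `[[`, numeric(1L), "loglik"))]]

  ## final E-step quantities at the returned parameters
  llmat <- .gbtm_llmat(dat, em$beta, em$sigma) +
    .gbtm_logpi(dat, em$pi, em$gamma)
  lse <- row_logsumexp(llmat)
  loglik <- sum(lse)
  post <- exp(llmat - lse)

  ## relabel groups in decreasing share order (stable labels)
  shares <- colMeans(post)
  ord <- order(shares, decreasing = TRUE)
  post <- post[, ord, drop = FALSE]
  beta <- em$beta[ord, , , drop = FALSE]
  pi <- em$pi[ord]
  gamma <- em$gamma
  if (!is.null(gamma)) {
    gamma <- gamma[ord, , drop = FALSE]
    gamma <- sweep(gamma, 2L, gamma[1L, ])
  }
  assignment <- max.col(post, ties.method = "first")
  shares <- colMeans(post)
  avepp <- vapply(seq_len(K), function(k) {
    sel <- assignment == k
    if (any(sel)) mean(post[sel, k]) else NA_real_
  }, numeric(1L))
  np <- gbtm_n_params(spec)

  structure(list(
    spec = spec, pi = pi, gamma = gamma, beta = beta, sigma = em$sigma,
    loglik = loglik, n_params = np,
    bic = gbtm_bic(loglik, np, dat$n),
    bic_obs = gbtm_bic(loglik, np, dat$n_obs),
    posterior = post, assignment = assignment,
    children = dat$children,
    group_shares = shares, avepp = avepp,
    entropy = relative_entropy(post, K),
    empty_groups = any(tabulate(assignment, K) == 0L),
    converged = em$converged, loglik_trace = em$trace,
    n_children = dat$n, n_obs = dat$n_obs,
    n_starts_used = length(parts), seed = seed),
    class = "gbtm_fit")
}

#' Fitted group mean trajectories
#'
#' @param fit a `gbtm_fit`.
#' @param months months at which to evaluate the polynomial means.
#' @return array `K x outcome x month` of log1p-scale means.
#' @export
trajectory_means <- function(fit, months = 0:14) {
  V <- outer(months, 0:fit$spec$poly_order, `^`)
  K <- fit$spec$n_groups
  no <- length(fit$spec$outcomes)
  out <- array(NA_real_, c(K, no, length(months)),
               dimnames = list(NULL, fit$spec$outcomes,
                               as.character(months)))
  for (k in seq_len(K)) for (o in seq_len(no))
    out[k, o, ] <- V %*% fit$beta[k, o, ]
  out
}

#' @export
print.gbtm_fit <- function(x, ...) {
  cat(sprintf(
    "Censored-normal GBTM: K=%d, order %d, n=%d children (%d obs)\n",
    x$spec$n_groups, x$spec$poly_order, x$n_children, x$n_obs))
  cat(sprintf("  loglik %.2f | BIC %.2f | entropy %.3f | converged: %s\n",
              x$loglik, x$bic, x$entropy, x$converged))
  cat("  shares:", paste(sprintf("%.3f", x$group_shares), collapse = " "),
      "\n")
  cat("  AvePP :", paste(sprintf("%.3f", x$avepp), collapse = " "), "\n")
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' @param fit a `gbtm_fit`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gbtm_fit <- function(fit, path) {
  out <- list(
    spec = list(n_groups = fit$spec$n_groups,
                poly_order = fit$spec$poly_order,
                outcomes = fit$spec$outcomes,
                membership_covariates = fit$spec$membership_covariates),
    pi = fit$pi, gamma = fit$gamma, beta = fit$beta, sigma = fit$sigma,
    loglik = fit$loglik, n_params = fit$n_params, bic = fit$bic,
    bic_obs = fit$bic_obs, group_shares = fit$group_shares,
    avepp = fit$avepp, entropy = fit$entropy,
    converged = fit$converged, n_starts_used = fit$n_starts_used,
    seed = fit$seed, n_children = fit$n_children, n_obs = fit$n_obs)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
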