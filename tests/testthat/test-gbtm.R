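test_that("the mixture log-likelihood matches brute-force enumeration", {
  coefs <- flat_coefs(c(1, 2, 2.5, 3), c(0.4, 1, 1.2, 2))
  mf <- make_frame(3, c(0, 6, 12), coefs, sigma = rep(0.5, 4),
                   assignment = c(1, 2, 1), seed = 7)
  spec <- gbtm_spec(2, 2)
  beta <- array(0, c(2, 4, 3))
  beta[1, , ] <- coefs[[1]]
  beta[2, , ] <- coefs[[2]]
  sigma <- c(0.5, 0.6, 0.5, 0.7)
  pi <- c(0.3, 0.7)
  got <- gbtm_loglik(mf, spec, beta, sigma, pi)
  want <- oracle_mixture_loglik(mf, pi, beta, sigma, outcome_bounds())
  expect_equal(got, want, tolerance = 1e-10)

  ## duplicating every child doubles the log-likelihood
  mf2 <- mf
  mf2$child_id <- paste0(mf2$child_id, "bis")
  expect_equal(gbtm_loglik(rbind(mf, mf2), spec, beta, sigma, pi),
               2 * got, tolerance = 1e-10)

  expect_error(gbtm_loglik(mf, spec, beta * NA, sigma, pi), "finite")
})

test_that("EM ascends and a K=1 fit without censoring equals OLS", {
  coefs <- flat_coefs(c(1.8, 3, 3, 2.5))
  coefs[[1]][, 2] <- -0.03  # gentle slopes keep values off the bounds
  mf <- make_frame(40, c(0, 3, 6, 12), coefs, sigma = rep(0.3, 4),
                   assignment = rep(1, 40), seed = 12)
  fit <- fit_gbtm(mf, gbtm_spec(1, 2), n_starts = 1, seed = 1, tol = 1e-9)
  expect_true(all(diff(fit$loglik_trace) >
                    -1e-8 * abs(fit$loglik_trace[-1])))
  expect_true(fit$converged)
  expect_equal(rowSums(fit$posterior), rep(1, fit$n_children))

  for (o in seq_along(c("ajc", "pga", "pge", "esr"))) {
    sub <- mf[as.integer(mf$outcome) == o, ]
    stopifnot(all(sub$y > 0))  # no observation on a bound
    ols <- unname(stats::coef(stats::lm(y ~ month + I(month^2),
                                        data = sub)))
    expect_equal(unname(fit$beta[1, o, ]), ols, tolerance = 1e-4)
  }
})

test_that("a censored K=1 fit agrees with survreg Tobit regressions", {
  ## push one outcome hard against the floor so censoring matters
  coefs <- flat_coefs(c(0.5, 2.5, 2.5, 2.2))
  coefs[[1]]["ajc", 2] <- -0.15
  mf <- make_frame(60, c(0, 3, 6, 12), coefs, sigma = rep(0.6, 4),
                   assignment = rep(1, 60), seed = 21)
  expect_gt(sum(mf$y[mf$outcome == "ajc"] == 0), 5)  # real censoring
  stopifnot(all(mf$y < outcome_bounds()$hi[as.character(mf$outcome)]))

  fit <- fit_gbtm(mf, gbtm_spec(1, 2), n_starts = 1, seed = 1,
                  tol = 1e-10, max_iter = 2000)
  b <- outcome_bounds()
  ll_surv <- 0
  for (o in c("ajc", "pga", "pge", "esr")) {
    sub <- mf[mf$outcome == o, ]
    event <- ifelse(sub$y <= 0, 0L, 1L)  # 0 = left-censored at the floor
    sr <- survival::survreg(
      survival::Surv(sub$y, event, type = "left") ~ month + I(month^2),
      data = sub, dist = "gaussian")
    ll_surv <- ll_surv + as.numeric(stats::logLik(sr))
    oi <- match(o, c("ajc", "pga", "pge", "esr"))
    if (o == "ajc")
      expect_equal(unname(fit$beta[1, oi, ]), unname(stats::coef(sr)),
                   tolerance = 0.02)
  }
  ## the summed independent Tobit log-likelihoods equal the K=1 mixture
  ## (no observation sits on an upper bound in this design)
  expect_equal(fit$loglik, ll_surv, tolerance = 1e-4)
})

test_that("well-separated groups are recovered exactly", {
  ## two flat trajectory groups separated by ten residual SDs
  coefs <- flat_coefs(c(3, 3, 3, 3), c(1, 1, 1, 1))
  mf <- make_frame(50, c(0, 6, 12), coefs, sigma = rep(0.2, 4),
                   assignment = rep(c(1, 2), 25), seed = 33)
  fit <- fit_gbtm(mf, gbtm_spec(2, 2), n_starts = 3, seed = 2)
  truth <- rep(c(1, 2), 25)
  expect_equal(oracle_ari(fit$assignment, truth), 1.0)
  ## labels come out in decreasing share order and posteriors are sharp
  expect_true(all(diff(fit$group_shares) <= 1e-12))
  expect_true(all(fit$avepp > 0.99))
})

test_that("fits are reproducible under a fixed seed", {
  coefs <- flat_coefs(c(2.5, 3, 3, 3), c(1, 1.2, 1, 1.5))
  mf <- make_frame(30, c(0, 6, 12), coefs, sigma = rep(0.4, 4),
                   assignment = rep(c(1, 2), 15), seed = 44)
  f1 <- fit_gbtm(mf, gbtm_spec(2, 2), n_starts = 3, seed = 9)
  f2 <- fit_gbtm(mf, gbtm_spec(2, 2), n_starts = 3, seed = 9)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$posterior, f2$posterior)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("relative entropy and BIC match their closed forms", {
  expect_equal(relative_entropy(rbind(c(1, 0), c(0, 1))), 1.0)
  expect_equal(relative_entropy(matrix(0.25, 3, 4)), 0.0)
  ## hand-computed two-child case:
  ## 1 - (0.3250830 + 0.6931472) / (2 log 2)
  post <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  hand <- 1 - (-(0.9 * log(0.9) + 0.1 * log(0.1)) + log(2)) / (2 * log(2))
  expect_equal(relative_entropy(post), hand, tolerance = 1e-12)
  expect_equal(relative_entropy(post), 0.2655022, tolerance = 1e-5)
  expect_equal(relative_entropy(matrix(1, 5, 1), K = 1), 1)

  expect_equal(gbtm_bic(-100, 10, 100), -100 - 5 * log(100),
               tolerance = 1e-9)
  expect_equal(gbtm_bic(-100, 10, 100), -123.0259, tolerance = 1e-4)
  expect_identical(gbtm_n_params(gbtm_spec(1, 1)), 12L)
  expect_identical(gbtm_n_params(gbtm_spec(6, 2)), 6L - 1L + 6L * 12L + 4L)
  ## heavier parameterisation always lowers BIC at fixed fit
  expect_lt(gbtm_bic(-100, 11, 100), gbtm_bic(-100, 10, 100))
})

test_that("membership covariates steer the mixing probabilities", {
  coefs <- flat_coefs(c(3, 3, 3, 3), c(1, 1, 1, 1))
  n <- 60
  ## covariate x strongly predicts group 1 membership
  x <- c(rep(1, 30), rep(0, 30))
  assignment <- ifelse(x == 1, 1L, 2L)
  mf <- make_frame(n, c(0, 6, 12), coefs, sigma = rep(0.3, 4),
                   assignment = assignment, seed = 55)
  covs <- data.frame(child_id = sprintf("C%03d", 1:n), x = x)
  spec <- gbtm_spec(2, 1, membership_covariates = "x")
  fit <- fit_gbtm(mf, spec, n_starts = 2, seed = 3, covariates = covs)
  expect_false(is.null(fit$gamma))
  expect_equal(dim(fit$gamma), c(2L, 2L))
  expect_equal(rowSums(fit$posterior), rep(1, n))
  ## group levels are identifiable: the slope on x must separate the
  ## groups in opposite directions with sizeable magnitude
  expect_gt(abs(fit$gamma[2, 2]), 2)
  expect_identical(gbtm_n_params(spec),
                   (2L - 1L) * 2L + 2L * 4L * 2L + 4L)
})

test_that("parameters are recovered from the six-template generator", {
  ## scaled-down parameter-recovery study: three seeded cohorts, correctly
  ## specified quadratic K=6 fits; mixing within binomial error, fitted
  ## month-0 and month-12 group means close to the generating polynomials
  tpl <- default_templates()
  share_err <- means_err <- numeric(0)
  for (s in c(101, 202, 303)) {
    cfg <- synthetic_config(n_children = 400, seed = s)
    co <- generate_cohort(cfg)
    prep <- preprocess_cohort(co)
    fit <- fit_gbtm(prep$model_frame, gbtm_spec(6, 2), n_starts = 6,
                    seed = s)
    truth <- prep$cohort$children$true_cluster[
      match(fit$children, prep$cohort$children$child_id)]
    ## map each fitted group to its dominant generating template
    tab <- table(fit$assignment, truth)
    map <- apply(tab, 1L, which.max)
    gen_share <- as.numeric(table(truth) / length(truth))
    for (k in seq_len(6)) {
      p <- gen_share[map[k]]
      se <- sqrt(p * (1 - p) / length(truth))
      share_err <- c(share_err,
                     abs(fit$group_shares[k] - p) / max(se, 1e-9))
    }
    tm <- trajectory_means(fit, months = c(0, 12))
    for (k in seq_len(6)) {
      want <- template_mean(tpl[[map[k]]], c(0, 12))
      means_err <- c(means_err, abs(tm[k, , ] - want))
    }
  }
  expect_lt(stats::median(share_err), 3)
  expect_lt(stats::median(means_err), 0.25)
})
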