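test_that("a 2x2 design reproduces the closed-form odds ratio", {
  ## cross-product odds ratio (10 * 10) / (20 * 20) = 0.25: the covariate
  ## is common in the reference cluster (20 of 30) and rare otherwise
  labels <- rep(c("ref", "other"), c(30, 30))
  x <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  covs <- data.frame(x = x)
  m <- fit_multinomial(covs, labels, reference = "ref")
  tab <- m$models$multivariable$table
  or <- tab$or[tab$term == "x"]
  expect_equal(or, 0.25, tolerance = 1e-4)
})

test_that("two-cluster multinomial agrees with binary logistic", {
  set.seed(13)
  n <- 300
  x1 <- rnorm(n)
  x2 <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x1 - 0.5 * x2))
  labels <- ifelse(y == 1, "case", "base")
  covs <- data.frame(x1 = x1, x2 = x2)
  m <- fit_multinomial(covs, labels, reference = "base")
  tab <- m$models$multivariable$table
  glm_fit <- stats::glm(y ~ x1 + x2, family = binomial())
  expect_equal(tab$estimate[match(c("(Intercept)", "x1", "x2"),
                                  tab$term)],
               unname(stats::coef(glm_fit)), tolerance = 1e-4)
  ## fitted probabilities behave like probabilities
  expect_equal(rowSums(m$fitted_probs), rep(1, nrow(m$fitted_probs)),
               tolerance = 1e-8)
})

test_that("an uninformative covariate yields an odds ratio near one", {
  set.seed(19)
  n <- 2000
  labels <- sample(c("a", "b"), n, replace = TRUE)
  covs <- data.frame(x = rnorm(n))
  m <- fit_multinomial(covs, labels, reference = "a")
  tab <- m$models$multivariable$table
  est <- tab$estimate[tab$term == "x"]
  se <- tab$se[tab$term == "x"]
  expect_lt(abs(est), 3 * se)
})

test_that("known multinomial-logit coefficients are recovered", {
  set.seed(29)
  n <- 5000
  x <- rnorm(n)
  eta <- cbind(0, -0.5 + 0.9 * x, 0.4 - 0.6 * x)
  p <- exp(eta) / rowSums(exp(eta))
  y <- apply(p, 1, function(pr) sample(c("r", "g2", "g3"), 1, prob = pr))
  m <- fit_multinomial(data.frame(x = x), y, reference = "r")
  tab <- m$models$multivariable$table
  truth <- c(g2 = 0.9, g3 = -0.6)
  for (cl in c("g2", "g3")) {
    row <- tab[tab$cluster == cl & tab$term == "x", ]
    expect_lt(abs(row$estimate - truth[[cl]]), 3 * row$se)
  }
  ## collinearity screen drops the duplicated covariate
  covs <- data.frame(x = x, x_copy = x + rnorm(n, 0, 1e-4),
                     z = rnorm(n))
  kept <- mtxtraj:::.collinearity_screen(covs, c("x", "x_copy", "z"))
  expect_true("z" %in% kept)
  expect_identical(length(kept), 2L)
})

test_that("rank-based AUC matches closed cases and the trapezoid oracle", {
  probs <- cbind(g1 = c(0.9, 0.8, 0.2, 0.1))
  expect_equal(unname(auc_one_vs_rest(probs, c("g1", "g1", "x", "x"))),
               1.0)
  probs <- cbind(g1 = rep(0.5, 6))
  expect_equal(unname(auc_one_vs_rest(probs, rep(c("g1", "x"), 3))), 0.5)
  ## scores (0.9, 0.8, 0.4) for labels (+, -, +): 1 of 2 ordered pairs
  probs <- cbind(g1 = c(0.9, 0.8, 0.4))
  expect_equal(unname(auc_one_vs_rest(probs, c("g1", "x", "g1"))), 0.5)
  ## absent cluster
  expect_true(is.na(auc_one_vs_rest(cbind(g9 = runif(5)),
                                    rep("a", 5))["g9"]))

  set.seed(31)
  for (i in 1:20) {
    score <- round(runif(40), 2)  # rounding forces ties
    pos <- rbinom(40, 1, 0.4) == 1
    if (!any(pos) || all(pos)) next
    got <- unname(auc_one_vs_rest(cbind(g = score),
                                  ifelse(pos, "g", "rest")))
    expect_equal(got, oracle_auc_trapezoid(score, pos),
                 tolerance = 1e-10)
  }
})

test_that("Kaplan-Meier estimates and log-rank behave as expected", {
  ## hand-computed product limit: events at t = 1 and 2 in a group of two
  km <- km_logrank(c(1, 2), c(1, 1), c("a", "a"))
  expect_equal(km$curves$a$surv, c(0.5, 0))
  expect_true(is.na(km$logrank_chisq))  # single group: no comparison

  ## two groups with identical event patterns
  km2 <- km_logrank(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                    rep(c("a", "b"), each = 3))
  expect_equal(km2$logrank_chisq, 0, tolerance = 1e-12)

  ## censoring only: survival stays at one, statistic undefined
  km3 <- km_logrank(c(5, 7, 9, 11), c(0, 0, 0, 0), rep(c("a", "b"), 2))
  expect_true(all(km3$curves$a$surv == 1))
  expect_true(is.na(km3$logrank_chisq))

  ## without censoring KM equals the empirical survival function
  set.seed(41)
  t <- sample(1:10, 30, replace = TRUE)
  km4 <- km_logrank(t, rep(1, 30), rep("a", 30))
  emp <- vapply(km4$curves$a$time, function(u) mean(t > u), 0)
  expect_equal(km4$curves$a$surv, emp, tolerance = 1e-12)
})

test_that("cluster descriptives use interpolated quantiles", {
  covs <- data.frame(child_id = sprintf("C%02d", 1:8),
                     age = c(1, 2, 3, 4, 5, 5, 5, NA),
                     sex = c(rep("f", 4), rep("m", 4)))
  lab <- rep(c("g1", "g2"), each = 4)
  d <- describe_clusters(covs, lab)
  age_g1 <- d$value[d$cluster == "g1" & d$variable == "age"]
  expect_match(age_g1, "^2\\.50 \\(1\\.75, 3\\.25\\)")  # median of 1:4
  age_g2 <- d[d$cluster == "g2" & d$variable == "age", ]
  expect_match(age_g2$value, "^5\\.00 \\(5\\.00, 5\\.00\\)")  # IQR width 0
  expect_equal(age_g2$pct_missing, 25)
  expect_equal(sum(d$n[d$variable == "sex"]), 8)
})
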