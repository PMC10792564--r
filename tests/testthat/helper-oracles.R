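## Independent oracles used across the suite.  These deliberately avoid
## the package's own code paths.

## Total probability of a censored normal: interior density integrated by
## quadrature plus the two boundary masses, all from stats:: primitives.
oracle_censnorm_mass <- function(mu, sigma, lo, hi) {
  interior <- stats::integrate(function(y)
    stats::dnorm(y, mu, sigma), lo, hi, rel.tol = 1e-10)$value
  interior + stats::pnorm(lo, mu, sigma) +
    stats::pnorm(hi, mu, sigma, lower.tail = FALSE)
}

## Brute-force mixture log-likelihood by direct enumeration of the group
## sum, written against the model definition rather than the package.
oracle_mixture_loglik <- function(model_frame, pi, beta, sigma, bounds) {
  children <- sort(unique(model_frame$child_id))
  K <- length(pi)
  total <- 0
  for (id in children) {
    rows <- model_frame[model_frame$child_id == id, , drop = FALSE]
    lik <- 0
    for (k in seq_len(K)) {
      lk <- log(pi[k])
      for (r in seq_len(nrow(rows))) {
        o <- as.character(rows$outcome[r])
        oi <- match(o, names(bounds$hi))
        mu <- sum(beta[k, oi, ] * rows$month[r]^(0:(dim(beta)[3] - 1)))
        y <- rows$y[r]
        lk <- lk + if (y <= bounds$lo[oi]) {
          stats::pnorm(bounds$lo[oi], mu, sigma[oi], log.p = TRUE)
        } else if (y >= bounds$hi[oi]) {
          stats::pnorm(bounds$hi[oi], mu, sigma[oi], log.p = TRUE,
                       lower.tail = FALSE)
        } else {
          stats::dnorm(y, mu, sigma[oi], log = TRUE)
        }
      }
      lik <- lik + exp(lk)
    }
    total <- total + log(lik)
  }
  total
}

## Trapezoidal AUC from an explicit ROC curve.
oracle_auc_trapezoid <- function(score, pos) {
  th <- sort(unique(score), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(score[pos] >= t), 0), 1)
  fpr <- c(0, vapply(th, function(t) mean(score[!pos] >= t), 0), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

## ACR Pedi decision recomputed from a qualitative pattern: for each core
## variable, "improve" (by at least the level), "stable", or "worsen"
## (by more than 30%).
oracle_acr_from_pattern <- function(pattern, level) {
  sum(pattern == "improve") >= 3 && sum(pattern == "worsen") <= 1
}

## Adjusted Rand index between two partitions.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

## One- or two-group flat trajectory coefficient sets.
flat_coefs <- function(levels1, levels2 = NULL) {
  c1 <- cbind(levels1, 0, 0)
  rownames(c1) <- c("ajc", "pga", "pge", "esr")
  out <- list(c1)
  if (!is.null(levels2)) {
    c2 <- cbind(levels2, 0, 0)
    rownames(c2) <- rownames(c1)
    out <- c(out, list(c2))
  }
  out
}

## Small model frame with all four outcomes observed at given months for
## n children, means supplied per (group, outcome) as polynomial coefs.
make_frame <- function(n, months, coef_list, sigma, assignment,
                       seed = 42) {
  set.seed(seed)
  b <- outcome_bounds()
  rows <- list()
  for (i in seq_len(n)) {
    k <- assignment[i]
    for (o in seq_along(OUTCOMES <- c("ajc", "pga", "pge", "esr"))) {
      mu <- vapply(months, function(t)
        sum(coef_list[[k]][o, ] * t^(0:(ncol(coef_list[[k]]) - 1))), 0)
      y <- pmin(pmax(mu + rnorm(length(months), 0, sigma[o]), b$lo[o]),
                b$hi[o])
      rows[[length(rows) + 1L]] <- data.frame(
        child_id = sprintf("C%03d", i), month = months,
        outcome = OUTCOMES[o], y = y)
    }
  }
  out <- do.call(rbind, rows)
  out$outcome <- factor(out$outcome, levels = c("ajc", "pga", "pge",
                                                "esr"))
  out
}

## Random complete core set on native scales.
random_core <- function() {
  c(pga_mm = sample(0:100, 1), pge_mm = sample(0:100, 1),
    chaq = sample(0:24, 1) / 8, ajc = sample(0:30, 1),
    limited_joint_count = sample(0:30, 1), esr = sample(0:120, 1))
}
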