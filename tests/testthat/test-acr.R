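test_that("percent change handles zero baselines as specified", {
  expect_equal(pct_change(10, 5), -50)
  expect_equal(pct_change(0, 0), 0)
  expect_identical(pct_change(0, 3), Inf)
  expect_equal(pct_change(c(10, 0), c(13, 1)), c(30, Inf))
  expect_error(pct_change(-1, 5), "non-negative")
})

core <- function(x) stats::setNames(rep(x, 6),
                                    c("pga_mm", "pge_mm", "chaq", "ajc",
                                      "limited_joint_count", "esr"))

test_that("composite response follows the 3-of-6 / one-worsening rule", {
  b <- c(pga_mm = 40, pge_mm = 40, chaq = 1, ajc = 4,
         limited_joint_count = 3, esr = 30)
  ## total response
  expect_true(acr_pedi(b, b * 0, 30))
  expect_true(acr_pedi(b, b * 0, 90))
  ## three variables improve 40%, one worsens 50%, two unchanged
  f <- b
  f[c("pga_mm", "pge_mm", "ajc")] <- b[c("pga_mm", "pge_mm", "ajc")] * 0.6
  f["esr"] <- b["esr"] * 1.5
  expect_true(acr_pedi(b, f, 30))
  expect_false(acr_pedi(b, f, 90))
  ## three variables improve 95% but two worsen 40%
  f <- b
  f[c("pga_mm", "pge_mm", "ajc")] <- b[c("pga_mm", "pge_mm", "ajc")] * 0.05
  f[c("chaq", "esr")] <- b[c("chaq", "esr")] * 1.4
  expect_false(acr_pedi(b, f, 30))
  expect_false(acr_pedi(b, f, 90))
  ## incomplete core sets are not evaluable, never FALSE
  f <- b
  f["chaq"] <- NA
  expect_true(is.na(acr_pedi(b, f, 30)))
})

test_that("classification agrees with the exhaustive pattern oracle", {
  ## all 3^6 qualitative patterns: improve exactly at the level (and a bit
  ## beyond), stay flat, or worsen just past 30%
  for (level in c(30, 90)) {
    states <- c("improve", "stable", "worsen")
    grid <- expand.grid(rep(list(states), 6), stringsAsFactors = FALSE)
    b <- core(100)
    for (i in seq_len(nrow(grid))) {
      pattern <- unlist(grid[i, ])
      mult <- ifelse(pattern == "improve", 1 - (level + 5) / 100,
                     ifelse(pattern == "stable", 1, 1.35))
      got <- acr_pedi(b, b * mult, level)
      expect_identical(got, oracle_acr_from_pattern(pattern, level))
    }
  }
})

test_that("ACR Pedi 90 implies ACR Pedi 30 and improves monotonically", {
  set.seed(77)
  for (i in 1:2000) {
    b <- random_core()
    f <- random_core()
    p30 <- acr_pedi(b, f, 30)
    p90 <- acr_pedi(b, f, 90)
    if (isTRUE(p90)) expect_true(p30)
    ## improving any single variable never destroys a positive response
    if (isTRUE(p30)) {
      v <- sample(names(f), 1)
      f2 <- f
      f2[v] <- f[v] * 0.5
      expect_true(acr_pedi(b, f2, 30))
    }
  }
})

test_that("window selection picks the nearest complete assessment", {
  vis <- data.frame(month = c(5L, 8L), t(sapply(c(1, 2), core)))
  names(vis)[-1] <- names(core(0))
  expect_identical(window_select(vis, "m6")$month, 5L)

  none <- vis[vis$month > 8, ]
  expect_null(window_select(none, "m6"))

  tie <- data.frame(month = c(5L, 7L), t(sapply(c(1, 2), core)))
  names(tie)[-1] <- names(core(0))
  expect_identical(window_select(tie, "m6")$month, 5L)

  ## incomplete assessments are skipped
  vis$chaq[1] <- NA
  expect_identical(window_select(vis, "m6")$month, 8L)
})

test_that("Wilson intervals match the score-test oracle", {
  got <- wilson_ci(8, 10)
  want <- stats::prop.test(8, 10, correct = FALSE)$conf.int
  expect_equal(got, as.numeric(want), tolerance = 1e-9)
  expect_equal(got, c(0.490, 0.943), tolerance = 1e-2)
  expect_equal(wilson_ci(0, 7)[1], 0)
  expect_equal(wilson_ci(10, 10)[2], 1)
  expect_true(all(is.na(wilson_ci(0, 0))))
})

test_that("scoring and cluster aggregation work end to end", {
  ## two children: one full responder, one not evaluable at 12 months
  visits <- data.frame(
    child_id = rep(c("A", "B"), each = 3),
    day = rep(c(0, 180, 365), 2),
    month = rep(c(0L, 6L, 12L), 2),
    ajc = c(10, 2, 0, 8, 8, NA),
    pga_mm = c(50, 10, 0, 60, 55, 50),
    pge_mm = c(40, 10, 0, 50, 50, 45),
    esr = c(30, 10, 5, 40, 38, 35),
    chaq = c(2, 0.5, 0, 1.5, 1.5, 1.5),
    limited_joint_count = c(6, 1, 0, 5, 5, 5),
    pain_mm = c(50, 10, 0, 60, 55, 50))
  cohort <- list(children = data.frame(child_id = c("A", "B")),
                 visits = visits)
  acr <- score_acr(cohort)
  expect_identical(nrow(acr), 4L)
  a6 <- acr[acr$child_id == "A" & acr$window == "m6", ]
  expect_true(a6$pedi30 && !a6$pedi90)
  a12 <- acr[acr$child_id == "A" & acr$window == "m12", ]
  expect_true(a12$pedi30 && a12$pedi90)
  b12 <- acr[acr$child_id == "B" & acr$window == "m12", ]
  expect_false(b12$evaluable)

  byc <- response_by_cluster(
    acr, data.frame(child_id = c("A", "B"), cluster = c("G1", "G2")))
  g1 <- byc[byc$cluster == "G1" & byc$window == "m12" & byc$level == 90, ]
  expect_equal(g1$proportion, 1)
  g2 <- byc[byc$cluster == "G2" & byc$window == "m12" & byc$level == 30, ]
  expect_identical(g2$n, 0L)
  expect_true(is.na(g2$proportion))
})
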