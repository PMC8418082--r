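test_that("Wilson interval matches hand-checked values and basic geometry", {
  z0 <- wilson(0, 10)
  expect_equal(z0$lower, 0, tolerance = 1e-3)
  w <- wilson(65, 422)
  expect_equal(round(w$lower, 2), 0.12)
  expect_equal(round(w$upper, 2), 0.19)
  m <- wilson(34, 35)
  expect_equal(round(m$estimate, 2), 0.92)
  # interval contains both the midpoint and the MLE
  for (xn in list(c(3, 10), c(0, 7), c(7, 7), c(34, 35))) {
    wi <- wilson(xn[1], xn[2])
    expect_lte(wi$lower, wi$estimate); expect_gte(wi$upper, wi$estimate)
    expect_lte(wi$lower, wi$mle); expect_gte(wi$upper, wi$mle)
  }
  # width shrinks toward 0 with n at fixed proportion
  widths <- sapply(c(10, 100, 1000, 10000),
                   function(n) { wi <- wilson(0.8 * n, n); wi$upper - wi$lower })
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[4], 0.02)
  expect_error(wilson(1, 0), "positive")
})

test_that("ANOVA ICC handles degenerate configurations and recovers the
           beta-binomial parameter", {
  allsingle <- data.frame(n_events = rep(1, 20),
                          n_detected = rbinom(20, 1, 0.5))
  expect_equal(icc_anova(allsingle), 0)
  perfect <- data.frame(n_events = c(3, 3), n_detected = c(3, 0))
  expect_equal(icc_anova(perfect), 1)
  alldet <- data.frame(n_events = c(2, 4, 1), n_detected = c(2, 4, 1))
  expect_equal(icc_anova(alldet), 0)
  # parameter recovery: beta-binomial clusters with true rho = 0.3
  set.seed(77)
  rho <- 0.3; mu <- 0.7
  ab <- 1 / rho - 1
  m <- sample(2:6, 50, replace = TRUE)
  p <- rbeta(50, mu * ab, (1 - mu) * ab)
  x <- rbinom(50, m, p)
  est <- icc_anova(data.frame(n_events = m, n_detected = x))
  expect_lt(abs(est - rho), 0.15)
})

test_that("cluster correction reduces to plain Wilson at DE = 1 and never
           narrows the interval", {
  oc <- data.frame(n_events = rep(1, 35), n_detected = c(rep(1, 34), 0))
  cw <- corrected_sensitivity(oc)
  pw <- wilson(34, 35)
  expect_identical(cw$estimate, pw$estimate)
  expect_identical(cw$lower, pw$lower)
  expect_identical(cw$upper, pw$upper)
  expect_equal(cw$design_effect, 1)
  # clustered cohort: interval at least as wide as the naive one
  set.seed(5)
  m <- sample(1:5, 20, replace = TRUE)
  p <- rbeta(20, 0.6 * 1.5, 0.4 * 1.5)    # rho = 0.4
  x <- rbinom(20, m, p)
  oc2 <- data.frame(n_events = m, n_detected = x)
  cw2 <- corrected_sensitivity(oc2)
  pw2 <- wilson(sum(x), sum(m))
  expect_gte((cw2$upper - cw2$lower) - (pw2$upper - pw2$lower), 0)
})

test_that("all-detected clusters degenerate to DE = 1 (adult stratum case)", {
  oc <- data.frame(n_events = c(3, 2, 1, 4, 21), n_detected = c(3, 2, 1, 4, 21))
  cw <- corrected_sensitivity(oc)
  expect_equal(cw$design_effect, 1)
  expect_equal(round(corrected_sensitivity(
    data.frame(n_events = rep(1, 31), n_detected = rep(1, 31)))$estimate, 2),
    0.94)
})

test_that("precision uses Wilson with false alarms and Laplace without", {
  p <- precision_estimate(65, 357)
  expect_equal(round(p$estimate, 2), 0.15)
  expect_equal(p$method, "WILSON")
  l <- precision_estimate(19, 0)
  expect_equal(round(l$estimate, 2), 0.95)
  expect_equal(l$method, "LAPLACE")
  expect_equal(l$estimate, 20 / 21)
  # rule of succession stays below 1 and increases with successes
  est <- sapply(1:50, function(x) precision_estimate(x, 0)$estimate)
  expect_true(all(est < 1))
  expect_true(all(diff(est) > 0))
  expect_error(precision_estimate(0, 0), "no alerts")
})

test_that("bootstrap FAR interval: degenerate inputs and determinism", {
  expect_warning(one <- far_bootstrap_ci(2, 48, n_iterations = 1000),
                 "degenerate")
  expect_equal(one$estimate, 1)
  expect_equal(one$lower, 1)
  expect_equal(one$upper, 1)
  # identical sessions: zero-width interval
  same <- far_bootstrap_ci(rep(3, 10), rep(24, 10), n_iterations = 2000,
                           seed = 1)
  expect_equal(same$lower, same$upper)
  expect_equal(same$estimate, 3)
  # seeded reproducibility
  a <- far_bootstrap_ci(c(0, 2, 5, 1), c(10, 20, 30, 40),
                        n_iterations = 3000, seed = 99)
  b <- far_bootstrap_ci(c(0, 2, 5, 1), c(10, 20, 30, 40),
                        n_iterations = 3000, seed = 99)
  expect_identical(a$lower, b$lower)
  expect_identical(a$upper, b$upper)
  # endpoints are achievable pooled-FAR values
  fa <- c(0, 2, 5, 1); hr <- c(10, 20, 30, 40)
  expect_gte(a$lower, min(24 * fa / hr))
  expect_lte(a$upper, max(24 * fa / hr))
})

test_that("exposure-adjusted rate test: symmetry, agreement with the exact
           test, and zero-event flag", {
  sym <- far_ratio_test(10, 100, 10, 100)
  expect_equal(sym$z, 0)
  expect_equal(sym$p_value, 1)
  zero <- far_ratio_test(0, 50, 0, 70)
  expect_equal(zero$p_value, 1)
  expect_equal(zero$flag, "no_events")
  # normal approximation tracks the exact binomial when counts are large
  for (case in list(c(30, 100, 25, 120), c(50, 300, 70, 250),
                    c(207, 3939, 150, 6357))) {
    pn <- far_ratio_test(case[1], case[2], case[3], case[4])$p_value
    pe <- far_ratio_test(case[1], case[2], case[3], case[4],
                         exact = TRUE)$p_value
    N <- case[1] + case[3]; pi0 <- case[2] / (case[2] + case[4])
    if (N * pi0 * (1 - pi0) >= 10) expect_lt(abs(pn - pe), 0.01)
  }
})

test_that("clustered difference test: identical groups give p = 1, unequal
           sensitivities are detected with high power", {
  g <- data.frame(n_events = c(2, 3, 1), n_detected = c(2, 2, 1))
  same <- clustered_diff_test(g, g)
  expect_equal(same$diff$estimate, 0)
  expect_equal(same$p_value, 1)
  # pediatric vs adult printed counts (singleton clusters): not significant
  oa <- data.frame(n_events = rep(1, 35), n_detected = c(rep(1, 34), 0))
  ob <- data.frame(n_events = rep(1, 31), n_detected = rep(1, 31))
  expect_gt(clustered_diff_test(oa, ob)$p_value, 0.05)
  # power: true sensitivities 0.95 vs 0.60, 30 clusters each
  set.seed(31)
  hits <- 0L
  for (r in 1:40) {
    mk <- function(p) {
      m <- sample(1:4, 30, replace = TRUE)
      data.frame(n_events = m, n_detected = rbinom(30, m, p))
    }
    if (clustered_diff_test(mk(0.95), mk(0.60))$p_value < 0.05) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 36L)                     # >= 90% of replicates
})

test_that("sample-size planner matches a brute-force width scan and is
           monotone", {
  z_width <- function(k, p, icc, mbar, conf = 0.95) {
    de <- 1 + (mbar - 1) * icc
    n_e <- k * mbar / de
    w <- wilson(p * n_e, n_e, conf)
    (w$upper - w$lower) / 2
  }
  brute <- function(p, h, icc, mbar) {
    k <- 1
    while (z_width(k, p, icc, mbar) > h) k <- k + 1
    k
  }
  for (case in list(list(p = 0.95, h = 0.05, icc = 0, m = 1),
                    list(p = 0.95, h = 0.05, icc = 0.3, m = 2),
                    list(p = 0.9, h = 0.1, icc = 0.2, m = 1.8),
                    list(p = 0.8, h = 0.07, icc = 0.5, m = 3))) {
    expect_equal(
      min_clusters_for_sensitivity(case$p, case$h, case$icc, case$m),
      brute(case$p, case$h, case$icc, case$m),
      info = paste(unlist(case), collapse = "/"))
  }
  # monotone: smaller halfwidth or larger icc never needs fewer clusters
  expect_gte(min_clusters_for_sensitivity(0.95, 0.05, 0.4, 2),
             min_clusters_for_sensitivity(0.95, 0.05, 0.2, 2))
  expect_gte(min_clusters_for_sensitivity(0.95, 0.03, 0.2, 2),
             min_clusters_for_sensitivity(0.95, 0.05, 0.2, 2))
})
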