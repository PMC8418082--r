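# Inference for clustered binary outcomes and event rates. Multiple seizures
# from one patient are correlated, which inflates the apparent precision of a
# pooled sensitivity; the correction estimates the intraclass correlation
# (ICC) of the per-event detection indicators, converts it to a design effect
# DE = 1 + (mbar - 1) * rho, and deflates the counts to effective sample
# sizes before applying the Wilson score interval.

interval_estimate <- function(estimate, lower, upper, confidence, method,
                              flag = NULL) {
  structure(list(estimate = estimate, lower = lower, upper = upper,
                 confidence = confidence, method = method, flag = flag),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%.4f [%.4f, %.4f] (%s, %.0f%%)%s\n", x$estimate, x$lower,
              x$upper, x$method, 100 * x$confidence,
              if (!is.null(x$flag)) paste0(" flag: ", x$flag) else ""))
  invisible(x)
}

#' Wilson score interval for a binomial proportion
#'
#' The returned point estimate is the Wilson midpoint
#' \eqn{(x + z^2/2)/(n + z^2)}; the raw proportion is returned in `$mle`.
#' Non-integer `x` and `n` are accepted (effective counts after a
#' design-effect deflation).
#'
#' @param x successes (0 <= x <= n).
#' @param n trials (> 0).
#' @param confidence confidence level (default 0.95).
#' @return an `interval_estimate` (`method = "WILSON"`).
#' @export
wilson <- function(x, n, confidence = 0.95) {
  if (n <= 0) stop("n must be positive")
  if (x < 0 || x > n) stop("x must lie in [0, n]")
  z <- stats::qnorm((1 + confidence) / 2)
  centre <- (x + z^2 / 2) / (n + z^2)
  hw <- z / (n + z^2) * sqrt(x * (n - x) / n + z^2 / 4)
  est <- interval_estimate(centre, max(0, centre - hw), min(1, centre + hw),
                           confidence, "WILSON")
  est$mle <- x / n
  est
}

#' ANOVA (Fleiss-type) intraclass correlation for clustered binary outcomes
#'
#' One-way ANOVA estimator on the per-event detection indicators grouped
#' by patient, clamped to \[0, 1\]. Degenerate configurations (a single
#' cluster, all clusters of size 1, or no between/within variability)
#' return 0; zero within-cluster variance with positive between-cluster
#' variance returns 1.
#'
#' @param outcomes `data.frame(n_events, n_detected)` with one row per
#'   cluster (patient); see [cluster_outcomes()].
#' @return estimated ICC in \[0, 1\].
#' @export
icc_anova <- function(outcomes) {
  m <- as.numeric(outcomes$n_events)
  x <- as.numeric(outcomes$n_detected)
  if (!length(m)) stop("no clusters")
  if (any(m < 1) || any(x < 0) || any(x > m)) stop("invalid cluster outcomes")
  k <- length(m)
  N <- sum(m)
  if (k == 1L || N == k) return(0)          # no replication structure
  p <- x / m
  pbar <- sum(x) / N
  msb <- sum(m * (p - pbar)^2) / (k - 1)
  msw <- sum(m * p * (1 - p)) / (N - k)     # binary within-cluster SS
  if (msw == 0 && msb == 0) return(0)       # all outcomes identical
  if (msw == 0) return(1)
  n0 <- (N - sum(m^2) / N) / (k - 1)
  rho <- (msb - msw) / (msb + (n0 - 1) * msw)
  min(1, max(0, rho))
}

#' Design effect for clustered binary outcomes
#'
#' \eqn{DE = 1 + (\bar m - 1)\hat\rho} with \eqn{\bar m} the unweighted
#' mean cluster size and \eqn{\hat\rho} from [icc_anova()].
#'
#' @inheritParams icc_anova
#' @return list `icc`, `mean_cluster_size`, `design_effect`.
#' @export
design_effect <- function(outcomes) {
  rho <- icc_anova(outcomes)
  mbar <- mean(outcomes$n_events)
  list(icc = rho, mean_cluster_size = mbar,
       design_effect = 1 + (mbar - 1) * rho)
}

#' Cluster-corrected sensitivity (Wilson interval on effective counts)
#'
#' Deflates the pooled counts by the design effect (`n_e = n/DE`,
#' `x_e = x/DE`) and applies the Wilson score interval to the effective
#' counts. With `DE = 1` (all clusters of size 1, or zero ICC) this is
#' identical to [wilson()] on the raw counts; the reported point estimate
#' is the Wilson midpoint, which is why the corrected sensitivity is
#' lower than the naive proportion when detection is near-perfect.
#'
#' @param outcomes per-patient cluster outcomes, see [cluster_outcomes()].
#' @param confidence confidence level.
#' @return an `interval_estimate` (`method = "WILSON_CLUSTER"`) with the
#'   design-effect diagnostics attached (`$icc`, `$design_effect`,
#'   `$n_effective`).
#' @export
corrected_sensitivity <- function(outcomes, confidence = 0.95) {
  n <- sum(outcomes$n_events)
  x <- sum(outcomes$n_detected)
  if (n < 1) stop("no events")
  de <- design_effect(outcomes)
  est <- wilson(x / de$design_effect, n / de$design_effect, confidence)
  est$method <- "WILSON_CLUSTER"
  est$icc <- de$icc
  est$design_effect <- de$design_effect
  est$n_effective <- n / de$design_effect
  est
}

#' Precision (positive predictive value) with Laplace fallback
#'
#' With at least one false alert the point estimate is the raw proportion
#' `tp / (tp + fa)` with a Wilson interval. With zero false alerts the
#' raw estimate of 1 is replaced by the Laplace rule-of-succession
#' estimate `(tp + 1) / (tp + 2)`, a conservative correction for a
#' proportion of exactly 1 at small sample size; the interval is the
#' Wilson interval on the Laplace-adjusted counts.
#'
#' @param n_true_alerts true positives.
#' @param n_false_alerts false alarms.
#' @param confidence confidence level.
#' @return an `interval_estimate` (`method` `"WILSON"` or `"LAPLACE"`).
#' @export
precision_estimate <- function(n_true_alerts, n_false_alerts,
                               confidence = 0.95) {
  tp <- n_true_alerts; fa <- n_false_alerts
  if (tp + fa < 1) stop("no alerts: precision undefined")
  if (fa > 0) {
    w <- wilson(tp, tp + fa, confidence)
    interval_estimate(tp / (tp + fa), w$lower, w$upper, confidence, "WILSON")
  } else {
    w <- wilson(tp + 1, tp + 2, confidence)
    interval_estimate((tp + 1) / (tp + 2), w$lower, w$upper, confidence,
                      "LAPLACE")
  }
}

#' Patient-level bootstrap percentile interval for the pooled FAR
#'
#' Resamples whole patients (sessions) with replacement, recomputes the
#' pooled FAR `24 * sum(FA) / sum(hours)` per replicate, and returns the
#' stated percentiles of the replicate distribution. Resampling at the
#' patient level keeps all within-patient variability inside each
#' resampled unit.
#'
#' @param false_alarms integer vector, false alarms per session.
#' @param hours numeric vector, worn hours per session.
#' @param n_iterations bootstrap replicates (default 1e5).
#' @param confidence confidence level; percentiles are
#'   `(1 - confidence)/2` and `1 - (1 - confidence)/2`.
#' @param seed optional integer seed for reproducibility.
#' @return an `interval_estimate` (`method = "BOOTSTRAP_PERCENTILE"`).
#'   A single-session input yields the degenerate interval
#'   `[point, point]` with `flag = "degenerate"` and a warning.
#' @export
far_bootstrap_ci <- function(false_alarms, hours, n_iterations = 1e5,
                             confidence = 0.95, seed = NULL) {
  k <- length(false_alarms)
  stopifnot(k == length(hours), all(hours > 0), n_iterations >= 1)
  point <- 24 * sum(false_alarms) / sum(hours)
  if (k == 1L) {
    warning("single session: bootstrap interval is degenerate")
    return(interval_estimate(point, point, point, confidence,
                             "BOOTSTRAP_PERCENTILE", flag = "degenerate"))
  }
  if (!is.null(seed)) set.seed(seed)
  B <- as.integer(n_iterations)
  reps <- numeric(B)
  chunk <- max(1L, min(B, as.integer(2e7 / k)))
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    idx <- sample.int(k, k * b, replace = TRUE)
    dim(idx) <- c(k, b)
    fa_s <- colSums(matrix(false_alarms[idx], nrow = k))
    hr_s <- colSums(matrix(hours[idx], nrow = k))
    reps[(done + 1L):(done + b)] <- 24 * fa_s / hr_s
    done <- done + b
  }
  alpha <- (1 - confidence) / 2
  q <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE)
  interval_estimate(point, q[1], q[2], confidence, "BOOTSTRAP_PERCENTILE")
}

#' Normal-approximation interval for a FAR (Poisson counts)
#'
#' `24 * (FA +/- z * sqrt(FA)) / hours`, truncated below at 0. Used for
#' the per-point intervals on threshold-sweep curves, where the headline
#' patient-level bootstrap would be prohibitive.
#'
#' @param false_alarms total false alarms.
#' @param hours total worn hours.
#' @param confidence confidence level.
#' @return an `interval_estimate` (`method = "NORMAL_APPROX"`).
#' @export
far_normal_ci <- function(false_alarms, hours, confidence = 0.95) {
  stopifnot(hours > 0)
  z <- stats::qnorm((1 + confidence) / 2)
  interval_estimate(24 * false_alarms / hours,
                    max(0, 24 * (false_alarms - z * sqrt(false_alarms)) / hours),
                    24 * (false_alarms + z * sqrt(false_alarms)) / hours,
                    confidence, "NORMAL_APPROX")
}

#' Exposure-adjusted test of equal false-alarm rates in two groups
#'
#' Conditional on the total count `N = fa1 + fa2`, under the null of
#' equal rates `fa1 ~ Binomial(N, T1 / (T1 + T2))` where `T` are the
#' exposures. The two-sided p-value comes from the normal approximation
#' `z = (fa1 - N pi) / sqrt(N pi (1 - pi))`; `exact = TRUE` uses the
#' exact binomial test instead.
#'
#' @param fa1,hours1 false alarms and worn hours in group 1.
#' @param fa2,hours2 false alarms and worn hours in group 2.
#' @param exact use `binom.test()` instead of the normal approximation.
#' @return list `p_value`, `z` (NA when exact), `flag` (`"no_events"`
#'   when `fa1 + fa2 = 0`, in which case `p_value = 1`).
#' @export
far_ratio_test <- function(fa1, hours1, fa2, hours2, exact = FALSE) {
  stopifnot(hours1 > 0, hours2 > 0)
  N <- fa1 + fa2
  if (N == 0) return(list(p_value = 1, z = NA_real_, flag = "no_events"))
  pi0 <- hours1 / (hours1 + hours2)
  if (exact) {
    p <- stats::binom.test(fa1, N, pi0)$p.value
    return(list(p_value = p, z = NA_real_, flag = NULL))
  }
  z <- (fa1 - N * pi0) / sqrt(N * pi0 * (1 - pi0))
  list(p_value = 2 * stats::pnorm(-abs(z)), z = z, flag = NULL)
}

#' Difference of cluster-corrected sensitivities between two groups
#'
#' Computes the corrected sensitivity of each group, forms the
#' difference, and builds a normal-reference interval with variance equal
#' to the sum of the design-effect-inflated binomial variances
#' `DE * p(1-p) / n` evaluated at the corrected point estimates (the
#' Wilson midpoints, which keeps the variance positive when a group
#' detected every event). The null of equal sensitivities is rejected
#' when 0 lies outside the interval.
#'
#' @param groupA,groupB per-patient cluster outcomes
#'   (`data.frame(n_events, n_detected)`).
#' @param confidence confidence level.
#' @return list `diff` (an `interval_estimate` on the difference scale),
#'   `p_value`, and the two group estimates.
#' @export
clustered_diff_test <- function(groupA, groupB, confidence = 0.95) {
  ea <- corrected_sensitivity(groupA, confidence)
  eb <- corrected_sensitivity(groupB, confidence)
  na <- sum(groupA$n_events); nb <- sum(groupB$n_events)
  va <- ea$design_effect * ea$estimate * (1 - ea$estimate) / na
  vb <- eb$design_effect * eb$estimate * (1 - eb$estimate) / nb
  d <- ea$estimate - eb$estimate
  se <- sqrt(va + vb)
  if (se == 0) {
    return(list(diff = interval_estimate(d, d, d, confidence, "NORMAL_APPROX",
                                         flag = "degenerate"),
                p_value = 1, groupA = ea, groupB = eb))
  }
  z <- stats::qnorm((1 + confidence) / 2)
  list(diff = interval_estimate(d, d - z * se, d + z * se, confidence,
                                "NORMAL_APPROX"),
       p_value = 2 * stats::pnorm(-abs(d) / se),
       groupA = ea, groupB = eb)
}

#' Minimum number of clusters for a target Wilson half-width
#'
#' Smallest number of patients (clusters) such that the cluster-corrected
#' Wilson interval at the expected sensitivity has half-width at most
#' `ci_halfwidth`. The effective-count threshold is solved in closed form
#' from the Wilson half-width
#' \eqn{z \sqrt{p(1-p) n_e + z^2/4} / (n_e + z^2) \le h},
#' then inflated by the design effect and divided by the mean cluster
#' size. Monotone non-increasing in `ci_halfwidth` and non-decreasing in
#' `icc`.
#'
#' @param expected_sens anticipated sensitivity in (0, 1).
#' @param ci_halfwidth target interval half-width (> 0).
#' @param icc anticipated intraclass correlation in \[0, 1).
#' @param mean_cluster_size anticipated mean events per seizing patient
#'   (>= 1).
#' @param confidence confidence level.
#' @return integer number of clusters (patients with events).
#' @export
min_clusters_for_sensitivity <- function(expected_sens, ci_halfwidth,
                                         icc = 0, mean_cluster_size = 1,
                                         confidence = 0.95) {
  stopifnot(expected_sens > 0, expected_sens < 1, ci_halfwidth > 0,
            mean_cluster_size >= 1, icc >= 0, icc < 1)
  z <- stats::qnorm((1 + confidence) / 2)
  p <- expected_sens; h <- ci_halfwidth
  # h^2 (u + z^2)^2 >= z^2 (p(1-p) u + z^2/4), u = effective n
  a <- h^2
  b <- 2 * h^2 * z^2 - z^2 * p * (1 - p)
  cc <- h^2 * z^4 - z^4 / 4
  disc <- b^2 - 4 * a * cc
  u <- if (disc <= 0) 0 else (-b + sqrt(disc)) / (2 * a)
  de <- 1 + (mean_cluster_size - 1) * icc
  k <- ceiling(max(u, 0) * de / mean_cluster_size)
  max(1L, as.integer(k))
}
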