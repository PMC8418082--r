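---
title: "Evaluating wearable convulsive-seizure detection: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating wearable convulsive-seizure detection: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seizeval)
```

## The evaluation problem

Wrist-worn devices that combine tri-axial accelerometry (ACM) and
electrodermal activity (EDA) can detect generalized and focal-to-bilateral
tonic-clonic seizures — collectively, convulsive seizures (CS) — in real
time. Validating such a device in an epilepsy monitoring unit produces a
distinctive data structure: per patient, a wear-time exposure of tens to
hundreds of hours; a reference standard built by multiple human experts
reading video-EEG; a handful of seizures concentrated in a minority of
patients (so detection outcomes are *clustered* within patients); and alarm
streams at more than one operating point of the decision rule. `seizeval`
implements the full evaluation methodology for this design: adjudication,
alarm scoring, cluster-corrected inference, bootstrap rate intervals,
monitoring-stream ROC/PR curves, actigraphy rest detection, and synthetic
cohorts to exercise all of it.

## Reference standard: 2-of-3 adjudication

Three neurologists annotate seizure intervals independently. An event enters
the reference standard when at least two reviewers marked it
(`adjudicate()`, `min_supporting = 2`). Two choices are not fixed by the
majority rule itself and are exposed in `adjudication_config()`:

* **Grouping.** Annotations are grouped by the transitive closure of
  pairwise temporal overlap of the half-open intervals. Any positive
  intersection groups two annotations — the weakest assumption, since no
  agreement tolerance is part of the rule itself.
* **Pooling and type.** Consensus onset/offset are the element-wise
  *median* across the supporting reviewers (robust with three raters; an
  `earliest` rule is available). Whether the majority must also agree on
  the seizure *type* (GTC vs FBTC) is configurable
  (`require_type_agreement`); with agreement required, a 2-of-3 type
  majority decides, mirroring the event-level rule. Both behaviours are
  kept because a presence-only reading of the rule is equally defensible.

## Scoring: matching alarms to seizures

A seizure is *detected* when at least one alarm falls in its clinical
interval `[onset, offset)`; the first such alarm defines the detection
latency; additional alarms inside the same seizure are absorbed — they are
neither true positives nor false alarms. Every alarm outside all consensus
seizures is exactly one false alarm. Absorption is forced by consistency:
counting intra-seizure repeats as false alarms would contradict the
definition of the true positive, and counting them as extra true positives
would break the event-denominator sensitivity. All intervals are half-open,
so a boundary alarm is never double-counted, and an alarm 0.1 s before
onset is a false alarm, not a detection.

Two endpoint families follow:

* **Sensitivity** = detected / labelled CS (event denominator, pooled over
  patients).
* **FAR** = 24 × false alarms / worn hours, the false-alarm burden per
  24 h of wear.

Rest stratification assigns a seizure to the rest stratum by its clinical
*onset* (onset is what determines whether an alert arrives while the
patient is unattended in bed); rest exposure is the intersection of wear
and detected-rest intervals, so rest and active strata partition hours,
alarms and seizures exactly.

## Cluster-corrected inference

Detection outcomes from the same patient are correlated. The correction
estimates the intraclass correlation of the per-event binary indicators
with the one-way ANOVA (Fleiss-type) estimator, clamped to [0, 1]
(`icc_anova()`), forms the design effect `DE = 1 + (m̄ − 1)ρ̂` with `m̄`
the unweighted mean events per seizing patient, deflates counts to
effective sizes `x/DE`, `n/DE`, and applies the Wilson score interval
(`corrected_sensitivity()`). The reported point estimate is the Wilson
*midpoint* `(x + z²/2)/(n + z²)`, which is why the corrected sensitivity
(e.g. 0.96 at 65/66) sits below the raw proportion (0.98) even when
`DE = 1`: the midpoint shrinks extreme proportions toward 1/2 by design.
Degenerate configurations — all clusters of size one, a single cluster, or
zero within-cluster variance with zero between-cluster variance (every
event detected) — return `ρ̂ = 0`, so the correction reduces *exactly* to
the plain Wilson interval; this identity is enforced bit-for-bit in the
tests.

**Precision** is true alerts / all alerts with a Wilson interval; with
zero false alarms the raw estimate of 1 is replaced by the Laplace rule of
succession `(x + 1)/(x + 2)` — a deliberately conservative estimate for a
proportion of exactly 1 at small n — with the Wilson interval taken on the
adjusted counts.

**FAR intervals** resample whole patients with replacement
(`far_bootstrap_ci()`, default 100,000 replicates, percentile method at
2.5/97.5), because the FAR distribution is right-skewed and within-patient
false alarms are far from Poisson-homogeneous. The generator is seedable;
tests and curve sweeps use smaller replicate counts (2,000–5,000), and the
per-point curve intervals use the cheaper Poisson normal approximation
`24(FA ± z√FA)/hours` (`far_normal_ci()`).

**Group comparisons.** Equality of FARs between groups with different
exposure is tested conditionally: given the total count `N`, the group-1
count is Binomial(N, T₁/(T₁+T₂)) under the null; the normal approximation
is the default with the exact binomial as an option, and the two agree
within 0.01 whenever `Nπ(1−π) ≥ 10`. Sensitivity differences use the
difference of corrected estimates with variance the sum of DE-inflated
binomial variances; the variance is evaluated at the corrected (midpoint)
estimates so that a group that detected every event still contributes
positive variance rather than degenerating the test.

**Sample-size planning** (`min_clusters_for_sensitivity()`) inverts the
Wilson half-width in closed form at the anticipated sensitivity, inflates
by the design effect, and divides by the mean cluster size; a brute-force
width scan verifies the closed form in the tests. The anticipated ICC is
an explicit input — planning numbers are meaningless without stating it.

## ROC and PR curves for a monitoring stream

Specificity has no natural denominator in continuous monitoring. Following
the pseudo-negative construction, non-seizure time is tiled into
`floor(non-seizure seconds / mean CS duration)` virtual negative events
(`pseudo_negatives()`), pooled over the cohort (a per-patient variant is a
configuration choice we did not take, as the pooled count is what the
specificity denominator needs). At realistic cohort scale (~10⁴ hours,
~85 s mean CS duration) there are ~4×10⁵ negatives, so specificity is
pinned near 0.999 for any plausible false-alarm count — the PR curve, not
the ROC, carries the usable information, which is exactly why both are
produced. `sweep_thresholds()` takes any `count_fn(threshold)` interface,
uses a default grid of 101 evenly spaced thresholds (the grid is not
dictated by anything; 101 gives 0.01 resolution), and attaches per-point
(not simultaneous) Wilson and normal-approximation bands.

## Rest detection

`activity_counts()` band-pass filters the ACM magnitude (zero-phase
Butterworth, order 2, 0.25–3 Hz) and counts upward crossings of a 0.02 g
threshold per 30-s epoch; `detect_rest()` applies a centred 30-min moving
average and thresholds it at 10 counts/epoch, then merges rest periods
less than 2 h apart. Upward-only crossings follow standard actigraphy
convention (counting both directions doubles every count); zero-phase
filtering avoids biasing rest onset/offset, which feed the stratification.
The three numeric parameters (band corners, crossing threshold, count
threshold) have no published values — the underlying commercial algorithm
is proprietary — so they were fixed once such that the synthetic
generator's scheduled sleep is recovered, and all are exposed in
`rest_config()`. Recovering any particular cohort's rest fraction is
therefore a calibration exercise, not a validation of these defaults.

## The surrogate detector

The commercial detection algorithm (a trained classifier over 40
proprietary ACM/EDA features) is not public. `detect_alarms()` implements
only its published architecture — 10-s windows with 75% overlap (2.5-s
stride), a per-window probability, and a thresholded decision rule with a
more sensitive and a more specific operating point — with a transparent
logistic score over four interpretable features: clonic-band (2–6 Hz) ACM
energy, rhythmicity (regularity of RMS-level crossings, which separates a
sustained clonic burst from equal-energy diffuse movement), EDA level and
EDA slope. A 180-s refractory period suppresses alarm trains from a single
event; the value is a contract choice, long enough that one seizure yields
one alarm and short enough not to mask a subsequent seizure. The surrogate
exists to exercise the pipeline and generate curves; nothing in this
package claims it reproduces the commercial algorithm's performance.

## Synthetic cohorts: what they emulate and what they do not

`simulate_event_cohort()` fixes its defaults to the published test-cohort
structure: 152 patients, seizing probability 36/152, zero-truncated
geometric event counts with mean 66/36, mean detection probability 65/66,
FA rate 0.83/24 h, ~38% rest, latencies ~N(37.46, 21.09) truncated at 0,
durations ~N(84.56, 34.57) truncated at 20 s. Two latent quantities are
not derivable from printed aggregates and were fixed once: the detection
ICC (0.2, a plausible within-patient correlation for this design) and the
gamma dispersion of per-patient FA rates (shape 1, i.e. exponential
mixing, which makes roughly half the cohort alarm-free — consistent with
the reported share of patients with zero false alarms). Active-mode alarms
are a thinned subset of the sensitive mode's alarms with retention
probabilities equal to the printed count ratios (113/357 for false alarms,
63/65 for detections), preserving the nesting property of a thresholded
decision rule.

The generator reproduces the statistical structure the estimators are
sensitive to — clustering, exposure heterogeneity, rate over-dispersion,
rest/active scheduling — and nothing else. Real data differ in ways the
generator does not attempt: seizure timing is not uniform over wear time,
false alarms co-occur with activity bouts rather than landing uniformly,
reviewer errors are not independent across events, and motif shape varies
across patients. Passing tests therefore validate the *methodology*, not
any device's field performance.

## Numerical conventions

* Timestamps are UTC seconds; all intervals half-open `[start, end)`;
  durations stay in seconds until the reporting boundary converts to
  hours.
* Alarms outside wear intervals are construction-time errors, never
  silently dropped.
* Report tables round half-to-even at 2 decimals at render time only.
* Every stochastic operation (bootstrap, generators) takes an explicit
  seed; identical seed and parameters give identical output.
* Problem sizes used in the test suite: 1,000 random sessions for the
  matcher oracle, exhaustive `x ≤ n ≤ 60` for the Wilson identity,
  100 cohorts × 5,000 replicates for bootstrap coverage, 200–500 clusters
  for ICC recovery, and 12–24 h synthetic signals for the actigraphy and
  detector checks. These sizes give stable checks at interactive runtimes.

## A worked example

```{r example, eval = FALSE}
co <- simulate_event_cohort(cohort_params(seed = 7))
fda <- score_cohort(co$sessions, mode = "FDA_CLEARED")
pooled_sensitivity(fda)
pooled_far(fda)
corrected_sensitivity(cluster_outcomes(fda))
performance_report(co$sessions, co$rest_intervals,
                   bootstrap_iterations = 10000, seed = 7)
group_tests(co$sessions, co$rest_intervals)
```

## Known limitations

* The ANOVA ICC on binary indicators is the canonical estimator for this
  design but is noisy below ~30 seizing patients; the corrected interval
  inherits that noise.
* Percentile bootstrap intervals undercover slightly at strong rate
  heterogeneity; the coverage property test quantifies this at the study's
  scale.
* Rest-condition corrected sensitivity depends on per-patient cluster
  sizes, which aggregate counts do not determine; it is covered by
  property tests rather than exact value checks.
* The EARLIEST pooling rule can, with transitively-grouped but not
  mutually overlapping annotations, produce an offset before the onset; it
  falls back to the latest supporting offset in that case.
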