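# Synthetic cohorts and signals. Event-level generation (patients, wear
# time, clustered seizure detection outcomes, heterogeneous false-alarm
# rates) is decoupled from signal-level generation (ACM/EDA streams with
# clonic motifs), so statistics tests never pay the signal-synthesis cost.
# Defaults encode the published test-cohort structure: 152 patients of whom
# 36 seize, 66 consensus seizures, pooled detection 65/66, pooled FAR
# 0.83/24 h, ~38% of wear time at rest, latencies ~N(37.46, 21.09) s, and
# seizure durations ~N(84.56, 34.57) s.

#' Event-level cohort generator parameters
#'
#' Per-patient detection probabilities are Beta-distributed with the
#' given mean and intraclass correlation `ICC = 1 / (alpha + beta + 1)`
#' (beta-binomial clustering); per-patient false-alarm rates are
#' Gamma-mixed Poisson (negative-binomial counts over exposure).
#'
#' @param n_patients cohort size.
#' @param p_seizing probability a patient experiences at least one
#'   consensus seizure.
#' @param events_mean mean events per seizing patient (zero-truncated
#'   geometric).
#' @param detection_prob_mean mean per-event detection probability.
#' @param detection_icc within-patient correlation of detection outcomes
#'   in \[0, 1).
#' @param fa_rate_mean mean false-alarm rate per 24 h worn.
#' @param fa_dispersion Gamma shape of the per-patient rate mixing
#'   distribution (smaller = more heterogeneous).
#' @param hours_mean,hours_sdlog mean worn hours and log-sd of the
#'   lognormal wear-duration distribution.
#' @param rest_fraction fraction of each day spent at rest.
#' @param latency_mean,latency_sd detection-latency distribution
#'   (truncated normal, floor 0) in seconds.
#' @param duration_mean,duration_sd seizure-duration distribution
#'   (truncated normal, floor 20 s) in seconds.
#' @param active_fa_retention,active_detection_retention probability that
#'   an FDA-mode false alarm (resp. detection alarm) is retained at the
#'   more specific Active operating point.
#' @param seed integer seed; identical parameters and seed give identical
#'   cohorts.
#' @return a `cohort_params` list.
#' @export
cohort_params <- function(n_patients = 152,
                          p_seizing = 36 / 152,
                          events_mean = 66 / 36,
                          detection_prob_mean = 65 / 66,
                          detection_icc = 0.2,
                          fa_rate_mean = 0.83,
                          fa_dispersion = 1,
                          hours_mean = 68,
                          hours_sdlog = 0.6,
                          rest_fraction = 0.388,
                          latency_mean = 37.46,
                          latency_sd = 21.09,
                          duration_mean = 84.56,
                          duration_sd = 34.57,
                          active_fa_retention = 113 / 357,
                          active_detection_retention = 63 / 65,
                          seed = 1L) {
  stopifnot(n_patients >= 1, p_seizing >= 0, p_seizing <= 1,
            events_mean >= 1, detection_prob_mean > 0,
            detection_prob_mean <= 1, detection_icc >= 0, detection_icc < 1,
            fa_rate_mean >= 0, fa_dispersion > 0, hours_mean > 0,
            rest_fraction >= 0, rest_fraction < 1)
  structure(as.list(environment()), class = "cohort_params")
}

rtrunc_norm <- function(n, mean, sd, lo = 0) pmax(lo, stats::rnorm(n, mean, sd))

# zero-truncated geometric with the given mean (support 1, 2, ...)
rztgeom <- function(n, mean) {
  q <- 1 - 1 / mean
  if (q <= 0) return(rep(1L, n))
  1L + stats::rgeom(n, 1 - q)
}

#' Simulate an event-level cohort
#'
#' Draws, per patient: worn hours (lognormal), seizure count (zero with
#' probability `1 - p_seizing`, else zero-truncated geometric), a
#' patient-level detection probability (Beta with the configured mean and
#' ICC), Bernoulli detection of each event, and a Gamma-mixed Poisson
#' false-alarm count over the exposure. Seizures are placed without
#' overlap over the wear interval; each detected seizure receives one
#' alarm at onset + latency, and false alarms are placed uniformly over
#' non-seizure wear time. Alarms carry both operating modes with Active
#' alarms a thinned subset of FDA alarms. Nightly rest blocks covering
#' `rest_fraction` of each day are recorded alongside.
#'
#' @param params a [cohort_params()].
#' @return list with `sessions` (list of [recording_session()]),
#'   `rest_intervals` (parallel list of interval tables), and `truth`
#'   (per-patient latent parameters and counts).
#' @export
simulate_event_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  p <- params
  mulog <- log(p$hours_mean) - p$hours_sdlog^2 / 2
  # Beta mixing for detection probabilities
  if (p$detection_icc > 0 && p$detection_prob_mean < 1) {
    ab <- 1 / p$detection_icc - 1
    al <- p$detection_prob_mean * ab
    be <- ab - al
  } else {
    al <- be <- NULL                     # degenerate: constant probability
  }
  sessions <- vector("list", p$n_patients)
  rest_intervals <- vector("list", p$n_patients)
  truth <- vector("list", p$n_patients)
  for (i in seq_len(p$n_patients)) {
    hours <- stats::rlnorm(1, mulog, p$hours_sdlog)
    dur_s <- hours * 3600
    age <- if (stats::runif(1) < 85 / 152) sample(6:20, 1) else sample(21:63, 1)
    n_ev <- if (stats::runif(1) < p$p_seizing) rztgeom(1, p$events_mean) else 0L
    pdet <- if (is.null(al)) p$detection_prob_mean else stats::rbeta(1, al, be)

    seiz <- NULL
    alarms <- NULL
    if (n_ev > 0L) {
      sdur <- rtrunc_norm(n_ev, p$duration_mean, p$duration_sd, lo = 20)
      # non-overlapping placement by sorting onsets and nudging collisions
      onset <- sort(stats::runif(n_ev, 0, max(1, dur_s - max(sdur) - 1)))
      if (n_ev > 1L) {
        for (j in 2:n_ev) {
          onset[j] <- max(onset[j], onset[j - 1] + sdur[j - 1] + 60)
        }
      }
      keep <- onset + sdur < dur_s
      onset <- onset[keep]; sdur <- sdur[keep]; n_ev <- sum(keep)
      if (n_ev == 0L) n_ev <- 0L
      if (n_ev > 0L) {
        type <- sample(CS_TYPES, n_ev, replace = TRUE, prob = c(12, 54))
        seiz <- data.frame(onset = onset, offset = onset + sdur,
                           type = type, n_supporting = sample(2:3, n_ev, TRUE))
        det <- stats::runif(n_ev) < pdet
        lat <- rtrunc_norm(n_ev, p$latency_mean, p$latency_sd)
        lat <- pmin(lat, sdur * 0.95)    # the alarm must fall inside the event
        at <- onset[det] + lat[det]
        if (length(at)) {
          keep_active <- stats::runif(length(at)) < p$active_detection_retention
          alarms <- data.frame(time = c(at, at[keep_active]),
                               mode = c(rep("FDA_CLEARED", length(at)),
                                        rep("ACTIVE", sum(keep_active))))
        }
      }
    }
    # false alarms: gamma-mixed Poisson over the exposure, placed outside
    # seizure intervals
    rate_i <- stats::rgamma(1, shape = p$fa_dispersion,
                            rate = p$fa_dispersion / max(p$fa_rate_mean, 1e-12))
    n_fa <- if (p$fa_rate_mean == 0) 0L else stats::rpois(1, rate_i * hours / 24)
    if (n_fa > 0L) {
      ft <- stats::runif(n_fa, 0, dur_s)
      if (!is.null(seiz) && nrow(seiz)) {
        for (rep_try in 1:20) {
          bad <- in_intervals(ft, data.frame(start = seiz$onset, end = seiz$offset))
          if (!any(bad)) break
          ft[bad] <- stats::runif(sum(bad), 0, dur_s)
        }
        ft <- ft[!in_intervals(ft, data.frame(start = seiz$onset, end = seiz$offset))]
      }
      if (length(ft)) {
        keep_active <- stats::runif(length(ft)) < p$active_fa_retention
        fa_df <- data.frame(time = c(ft, ft[keep_active]),
                            mode = c(rep("FDA_CLEARED", length(ft)),
                                     rep("ACTIVE", sum(keep_active))))
        alarms <- if (is.null(alarms)) fa_df else rbind(alarms, fa_df)
      }
    }
    sessions[[i]] <- recording_session(
      patient_id = sprintf("P%03d", i), age_years = age,
      device = sample(c("E4", "EMBRACE"), 1, prob = c(124, 28)),
      wear_intervals = data.frame(start = 0, end = dur_s),
      alarms = alarms, seizures = seiz)
    # nightly rest: one block per day covering rest_fraction of 24 h
    n_days <- ceiling(dur_s / 86400)
    rs <- (seq_len(n_days) - 1) * 86400
    rest_intervals[[i]] <- intersect_intervals(
      data.frame(start = rs, end = rs + p$rest_fraction * 86400),
      data.frame(start = 0, end = dur_s))
    truth[[i]] <- data.frame(patient_id = sprintf("P%03d", i),
                             hours = hours, n_events = n_ev,
                             detection_prob = pdet, fa_rate = rate_i)
  }
  list(sessions = sessions, rest_intervals = rest_intervals,
       truth = do.call(rbind, truth))
}

#' Corrupt true events into three reviewers' annotations
#'
#' Each reviewer independently jitters onsets and offsets (normal noise,
#' truncated to keep offset > onset) and misses events with probability
#' `miss_prob`.
#'
#' @param true_events `data.frame(patient_id, onset, offset, type)`.
#' @param jitter_sd timing noise sd in seconds.
#' @param miss_prob per-reviewer miss probability (scalar or length 3).
#' @param seed integer seed.
#' @return annotation `data.frame` as accepted by [adjudicate()].
#' @export
reviewer_noise <- function(true_events, jitter_sd = 0, miss_prob = 0,
                           seed = 1L) {
  set.seed(seed)
  miss_prob <- rep_len(miss_prob, 3L)
  out <- lapply(1:3, function(r) {
    keep <- stats::runif(nrow(true_events)) >= miss_prob[r]
    ev <- true_events[keep, , drop = FALSE]
    if (!nrow(ev)) return(NULL)
    on <- ev$onset + stats::rnorm(nrow(ev), 0, jitter_sd)
    off <- ev$offset + stats::rnorm(nrow(ev), 0, jitter_sd)
    off <- pmax(off, on + 1)
    data.frame(reviewer_id = paste0("R", r),
               patient_id = ev$patient_id,
               onset = on, offset = off,
               seizure_type = ev$type)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(reviewer_id = character(0), patient_id = character(0),
                      onset = numeric(0), offset = numeric(0),
                      seizure_type = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Signal-level generator parameters
#'
#' @param duration_hours recording length.
#' @param rest_blocks interval table (seconds) of scheduled rest; the
#'   remainder of the record is active.
#' @param seizure_times onsets (seconds) of injected convulsive motifs.
#' @param clonic_freq clonic oscillation frequency in Hz (must lie in
#'   (2, 6), the band the surrogate detector scores).
#' @param motif_amplitude clonic amplitude in g.
#' @param motif_duration motif length in seconds.
#' @param eda_surge post-onset electrodermal surge amplitude in
#'   microsiemens.
#' @param eda_decay surge exponential decay constant in seconds.
#' @param artifact_rate short high-motion artifacts (tooth-brushing /
#'   clapping analogues) per hour of active time.
#' @param active_motion_sd movement noise sd in g during active blocks.
#' @param seed integer seed.
#' @return a `signal_params` list.
#' @export
signal_params <- function(duration_hours = 1,
                          rest_blocks = NULL,
                          seizure_times = numeric(0),
                          clonic_freq = 4,
                          motif_amplitude = 1,
                          motif_duration = 60,
                          eda_surge = 5,
                          eda_decay = 120,
                          artifact_rate = 0,
                          active_motion_sd = 0.15,
                          seed = 1L) {
  stopifnot(duration_hours > 0, motif_duration > 0,
            clonic_freq > 2, clonic_freq < 6)
  if (any(seizure_times < 0) ||
      any(seizure_times + motif_duration > duration_hours * 3600)) {
    stop("seizure_times outside the recording")
  }
  structure(as.list(environment()), class = "signal_params")
}

#' Simulate ACM and EDA streams with labelled events
#'
#' ACM (32 Hz, tri-axial, gravity on z) is baseline sensor noise plus
#' band-limited movement during active blocks, a sinusoidal clonic motif
#' at each seizure time, and sporadic short artifacts. EDA (4 Hz) is a
#' slow tonic drift plus an exponential phasic surge after each seizure
#' onset.
#'
#' @param params a [signal_params()].
#' @return list `acm` (`data.frame(t, x, y, z)`), `eda`
#'   (`data.frame(t, eda)`), `labels` (`data.frame(onset, offset, kind)`).
#' @export
simulate_signals <- function(params = signal_params()) {
  stopifnot(inherits(params, "signal_params"))
  set.seed(params$seed)
  p <- params
  fs_a <- 32; fs_e <- 4
  dur <- p$duration_hours * 3600
  ta <- seq(0, dur - 1 / fs_a, by = 1 / fs_a)
  te <- seq(0, dur - 1 / fs_e, by = 1 / fs_e)
  n <- length(ta)
  x <- stats::rnorm(n, 0, 0.01)
  y <- stats::rnorm(n, 0, 0.01)
  z <- 1 + stats::rnorm(n, 0, 0.01)

  active <- if (is.null(p$rest_blocks)) data.frame(start = 0, end = dur)
            else setdiff_intervals(data.frame(start = 0, end = dur),
                                   as_intervals(p$rest_blocks))
  labels <- data.frame(onset = numeric(0), offset = numeric(0),
                       kind = character(0))
  # irregular movement during active blocks (low-frequency, arrhythmic)
  for (i in seq_len(nrow(active))) {
    sel <- ta >= active$start[i] & ta < active$end[i]
    m <- sum(sel)
    if (m > 64) {
      mv <- stats::filter(stats::rnorm(m, 0, p$active_motion_sd),
                          rep(1 / 16, 16), circular = TRUE)
      # movement modulates the gravity-aligned axis so it shows in the
      # vector magnitude at its own frequency
      z[sel] <- z[sel] + as.numeric(mv)
      x[sel] <- x[sel] + as.numeric(stats::filter(
        stats::rnorm(m, 0, p$active_motion_sd), rep(1 / 16, 16),
        circular = TRUE))
    }
  }
  # sporadic rhythmic artifacts during active time (seizure-like but brief)
  if (p$artifact_rate > 0) {
    act_h <- sum(active$end - active$start) / 3600
    n_art <- stats::rpois(1, p$artifact_rate * act_h)
    if (n_art > 0) {
      for (k in seq_len(n_art)) {
        blk <- sample(nrow(active), 1, prob = active$end - active$start)
        a0 <- stats::runif(1, active$start[blk],
                           max(active$start[blk], active$end[blk] - 5))
        alen <- stats::runif(1, 2, 5)
        sel <- ta >= a0 & ta < a0 + alen
        f_art <- stats::runif(1, 3, 5)
        z[sel] <- z[sel] + 0.6 * p$motif_amplitude *
          sin(2 * pi * f_art * (ta[sel] - a0)) *
          (1 + 0.3 * stats::rnorm(sum(sel)))
        labels <- rbind(labels, data.frame(onset = a0, offset = a0 + alen,
                                           kind = "artifact"))
      }
    }
  }
  # clonic motifs
  eda <- 1 + 0.2 * sin(2 * pi * te / dur) + stats::rnorm(length(te), 0, 0.02)
  for (s0 in p$seizure_times) {
    sel <- ta >= s0 & ta < s0 + p$motif_duration
    env <- sin(pi * (ta[sel] - s0) / p$motif_duration)   # waxing-waning
    z[sel] <- z[sel] + p$motif_amplitude * env *
      sin(2 * pi * p$clonic_freq * (ta[sel] - s0))
    sele <- te >= s0 & te < s0 + 6 * p$eda_decay
    eda[sele] <- eda[sele] + p$eda_surge *
      (1 - exp(-(te[sele] - s0) / 10)) * exp(-(te[sele] - s0) / p$eda_decay)
    labels <- rbind(labels, data.frame(onset = s0,
                                       offset = s0 + p$motif_duration,
                                       kind = "seizure"))
  }
  list(acm = data.frame(t = ta, x = x, y = y, z = z),
       eda = data.frame(t = te, eda = pmax(0.01, eda)),
       labels = labels[order(labels$onset), , drop = FALSE])
}
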