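# Shared fixtures and the independent brute-force oracle for alarm matching.

# Printed aggregate counts of the published test cohort, used as fixtures.
paper_counts <- list(
  overall = list(hours = 10296, cs = 66, detected_fda = 65, fa_fda = 357,
                 detected_active = 63, fa_active = 113),
  pediatric = list(hours = 3939, cs = 35, detected_fda = 34, fa_fda = 207,
                   fa_active = 65),
  adult = list(hours = 6357, cs = 31, detected_fda = 31, fa_fda = 150,
               fa_active = 48),
  rest = list(hours = 3995, cs = 20, detected_fda = 19, fa_fda = 0)
)

# Brute-force matcher: enumerates every (alarm, seizure) pair. Kept
# deliberately independent of score_session's single pass.
brute_force_score <- function(seizures, alarm_times) {
  n_detected <- 0L
  latencies <- numeric(0)
  alarm_in_seizure <- rep(FALSE, length(alarm_times))
  for (i in seq_len(nrow(seizures))) {
    hits <- c()
    for (j in seq_along(alarm_times)) {
      if (alarm_times[j] >= seizures$onset[i] &&
          alarm_times[j] < seizures$offset[i]) {
        hits <- c(hits, j)
        alarm_in_seizure[j] <- TRUE
      }
    }
    if (length(hits)) {
      n_detected <- n_detected + 1L
      latencies <- c(latencies, min(alarm_times[hits]) - seizures$onset[i])
    }
  }
  list(n_detected = n_detected,
       latencies = sort(latencies),
       n_false_alarms = sum(!alarm_in_seizure))
}

# Random small session: <= max_events non-overlapping seizures and a
# handful of alarms anywhere in the wear interval.
random_session <- function(id, max_events = 10, wear_h = 48) {
  dur <- wear_h * 3600
  n_ev <- sample(0:max_events, 1)
  seiz <- NULL
  if (n_ev > 0) {
    onset <- sort(runif(n_ev, 0, dur - 400))
    if (n_ev > 1) {
      for (j in 2:n_ev) onset[j] <- max(onset[j], onset[j - 1] + 150)
    }
    len <- runif(n_ev, 30, 120)
    keep <- onset + len < dur
    if (any(keep)) {
      seiz <- data.frame(onset = onset[keep], offset = (onset + len)[keep],
                         type = "GTC", n_supporting = 3L)
    }
  }
  n_al <- sample(0:8, 1)
  alarms <- if (n_al > 0) {
    data.frame(time = runif(n_al, 0, dur), mode = "FDA_CLEARED")
  } else NULL
  recording_session(id, age_years = sample(6:60, 1), device = "E4",
                    wear_intervals = data.frame(start = 0, end = dur),
                    alarms = alarms, seizures = seiz)
}

# One-patient session carrying given counts, for pooled-rate fixtures.
counts_session <- function(id, hours, n_fa, mode = "FDA_CLEARED",
                           age = 30) {
  dur <- hours * 3600
  alarms <- if (n_fa > 0) {
    data.frame(time = seq(1, dur - 1, length.out = n_fa), mode = mode)
  } else NULL
  recording_session(id, age_years = age, device = "E4",
                    wear_intervals = data.frame(start = 0, end = dur),
                    alarms = alarms)
}

# Cohort of single-seizure sessions with x of n detected, for
# sensitivity fixtures (every cluster has size 1, so DE = 1).
singleton_cohort <- function(x, n, hours_each = 24) {
  lapply(seq_len(n), function(i) {
    detected <- i <= x
    seiz <- data.frame(onset = 1000, offset = 1100, type = "GTC",
                       n_supporting = 3L)
    alarms <- if (detected) {
      data.frame(time = 1030, mode = "FDA_CLEARED")
    } else NULL
    recording_session(sprintf("S%03d", i), age_years = 30, device = "E4",
                      wear_intervals = data.frame(start = 0,
                                                  end = hours_each * 3600),
                      alarms = alarms, seizures = seiz)
  })
}
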