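# Alarm-to-seizure matching. A consensus seizure counts as detected when at
# least one alarm falls between its clinical onset and clinical offset
# (half-open interval); the first such alarm defines the detection latency,
# further alarms inside the same seizure are absorbed (neither true positive
# nor false alarm), and every alarm outside all seizure intervals counts as
# exactly one false alarm.

#' Score one session at one operating mode
#'
#' @param session a [recording_session()] carrying consensus seizures and
#'   alarms.
#' @param mode operating-mode name to filter alarms on (`"FDA_CLEARED"`,
#'   `"ACTIVE"`), an [operating_point()], or `NULL` to use all alarms.
#' @param exclude_intervals optional interval table; alarms falling inside
#'   are ignored entirely (sensitivity-analysis hook, e.g. non-convulsive
#'   seizure periods).
#' @return object of class `scored_session`: patient id, seizure and
#'   detection counts, per-detection latencies (s), false-alarm count,
#'   worn hours, and the seizure durations (s).
#' @export
score_session <- function(session, mode = NULL, exclude_intervals = NULL) {
  stopifnot(inherits(session, "recording_session"))
  alarms <- session$alarms
  if (inherits(mode, "operating_point")) mode <- mode$name
  if (!is.null(mode) && nrow(alarms)) {
    alarms <- alarms[alarms$mode == mode, , drop = FALSE]
  }
  if (!is.null(exclude_intervals) && nrow(alarms)) {
    alarms <- alarms[!in_intervals(alarms$time, exclude_intervals), , drop = FALSE]
  }
  seiz <- session$seizures
  t <- sort(alarms$time)

  n_seiz <- nrow(seiz)
  detected <- logical(n_seiz)
  latencies <- numeric(0)
  used <- rep(FALSE, length(t))
  for (i in seq_len(n_seiz)) {
    inside <- which(t >= seiz$onset[i] & t < seiz$offset[i])
    if (length(inside)) {
      detected[i] <- TRUE
      latencies <- c(latencies, t[inside[1]] - seiz$onset[i])
      used[inside] <- TRUE             # absorbed: first is TP, rest neither
    }
  }
  structure(list(patient_id = session$patient_id,
                 age_group = session$age_group,
                 n_seizures = n_seiz,
                 n_detected = sum(detected),
                 detected = detected,
                 latencies = latencies,
                 n_false_alarms = sum(!used),
                 hours = total_hours(session),
                 durations = if (n_seiz) seiz$offset - seiz$onset else numeric(0)),
            class = "scored_session")
}

#' Aggregate scored sessions into a cohort score
#'
#' @param scored list of `scored_session` objects.
#' @return object of class `cohort_score` with a per-session table,
#'   pooled totals, all latencies and seizure durations.
#' @export
cohort_score <- function(scored) {
  stopifnot(length(scored) >= 1L,
            all(vapply(scored, inherits, logical(1), "scored_session")))
  tab <- data.frame(
    patient_id = vapply(scored, `[[`, character(1), "patient_id"),
    age_group = vapply(scored, `[[`, character(1), "age_group"),
    n_seizures = vapply(scored, `[[`, integer(1), "n_seizures"),
    n_detected = vapply(scored, function(s) as.integer(s$n_detected), integer(1)),
    n_false_alarms = vapply(scored, function(s) as.integer(s$n_false_alarms), integer(1)),
    hours = vapply(scored, `[[`, numeric(1), "hours"))
  durations <- unlist(lapply(scored, `[[`, "durations"))
  structure(list(
    sessions = tab,
    latencies = unlist(lapply(scored, `[[`, "latencies")),
    durations = durations,
    totals = list(seizures = sum(tab$n_seizures),
                  detected = sum(tab$n_detected),
                  false_alarms = sum(tab$n_false_alarms),
                  hours = sum(tab$hours)),
    mean_cs_duration = if (length(durations)) mean(durations) else NA_real_,
    sd_cs_duration = if (length(durations) > 1L) stats::sd(durations) else NA_real_),
    class = "cohort_score")
}

#' @export
print.cohort_score <- function(x, ...) {
  cat(sprintf(
    "<cohort_score> %d sessions, %.0f h; %d/%d CS detected; %d false alarms (FAR %.2f/24 h)\n",
    nrow(x$sessions), x$totals$hours, x$totals$detected, x$totals$seizures,
    x$totals$false_alarms,
    if (x$totals$hours > 0) 24 * x$totals$false_alarms / x$totals$hours else NA_real_))
  invisible(x)
}

#' Pooled sensitivity
#'
#' Number of detected consensus seizures divided by the number of
#' expert-labelled consensus seizures.
#'
#' @param cohort a `cohort_score`.
#' @return proportion in \[0, 1\].
#' @export
pooled_sensitivity <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_score"))
  if (cohort$totals$seizures < 1L) stop("no consensus seizures: sensitivity undefined")
  cohort$totals$detected / cohort$totals$seizures
}

#' Pooled false-alarm rate per 24 hours worn
#'
#' Total false alarms divided by total recording hours, normalised to
#' 24 h.
#'
#' @param cohort a `cohort_score`.
#' @return rate per 24 h-worn (>= 0).
#' @export
pooled_far <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_score"))
  if (cohort$totals$hours <= 0) stop("zero recording hours: FAR undefined")
  24 * cohort$totals$false_alarms / cohort$totals$hours
}

#' Detection-latency summary
#'
#' Seconds from clinical onset to the first in-seizure alarm. Returns the
#' mean and sample standard deviation, plus the median (reported
#' alongside the mean because summaries of skewed latencies are often
#' quoted both ways).
#'
#' @param cohort a `cohort_score`.
#' @return list `mean`, `sd`, `median`, `n`; `sd` is 0 with
#'   `degenerate = TRUE` when only one detection exists.
#' @export
latency_summary <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_score"))
  lat <- cohort$latencies
  if (!length(lat)) stop("no detected seizures: latency undefined")
  list(mean = mean(lat),
       sd = if (length(lat) > 1L) stats::sd(lat) else 0,
       median = stats::median(lat),
       n = length(lat),
       degenerate = length(lat) == 1L)
}

#' Per-patient cluster outcomes
#'
#' One row per patient who experienced at least one consensus seizure:
#' the number of events and the number detected. This is the input to the
#' intraclass-correlation / design-effect correction.
#'
#' @param cohort a `cohort_score`.
#' @return `data.frame(patient_id, n_events, n_detected)`.
#' @export
cluster_outcomes <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_score"))
  tab <- cohort$sessions[cohort$sessions$n_seizures > 0L, , drop = FALSE]
  data.frame(patient_id = tab$patient_id,
             n_events = tab$n_seizures,
             n_detected = tab$n_detected)
}

#' Split sessions by age group
#'
#' @param sessions list of `recording_session`.
#' @return named list `pediatric`, `adult` of session lists (possibly
#'   empty).
#' @export
stratify_age <- function(sessions) {
  grp <- vapply(sessions, `[[`, character(1), "age_group")
  list(pediatric = sessions[grp == "pediatric"],
       adult = sessions[grp == "adult"])
}

#' Restrict a session to (or away from) rest intervals
#'
#' The rest stratum keeps only wear time inside rest intervals as
#' exposure, only alarms inside rest intervals, and only seizures whose
#' clinical onset lies inside a rest interval (onset governs alerting
#' utility). `complement = TRUE` gives the active stratum. A session with
#' no overlap with the requested stratum returns `NULL`.
#'
#' @param session a `recording_session`.
#' @param rest_intervals interval table of detected rest for this
#'   session.
#' @param complement restrict to active (non-rest) time instead.
#' @return a `recording_session` or `NULL`.
#' @export
restrict_session <- function(session, rest_intervals, complement = FALSE) {
  stopifnot(inherits(session, "recording_session"))
  rest <- as_intervals(rest_intervals)
  keep <- if (complement) setdiff_intervals(session$wear_intervals, rest)
          else intersect_intervals(session$wear_intervals, rest)
  if (nrow(keep) == 0L) return(NULL)
  al <- session$alarms
  al <- al[in_intervals(al$time, keep), , drop = FALSE]
  se <- session$seizures
  se <- se[in_intervals(se$onset, keep), , drop = FALSE]
  s2 <- session
  s2$wear_intervals <- keep
  s2$alarms <- al
  s2$seizures <- se
  s2
}

#' Stratify sessions into rest and active cohorts
#'
#' @param sessions list of `recording_session`.
#' @param rest_list list of interval tables, parallel to `sessions`
#'   (entries may be empty tables).
#' @return named list `rest`, `active` of session lists. The two strata
#'   partition each session's exposure, alarms and seizures.
#' @export
stratify_rest <- function(sessions, rest_list) {
  stopifnot(length(sessions) == length(rest_list))
  empty <- data.frame(start = numeric(0), end = numeric(0))
  rest <- list(); active <- list()
  for (i in seq_along(sessions)) {
    ri <- rest_list[[i]]
    if (is.null(ri)) ri <- empty
    r <- restrict_session(sessions[[i]], ri, complement = FALSE)
    a <- restrict_session(sessions[[i]], ri, complement = TRUE)
    if (!is.null(r)) rest[[length(rest) + 1L]] <- r
    if (!is.null(a)) active[[length(active) + 1L]] <- a
  }
  list(rest = rest, active = active)
}

#' Score a list of sessions into a cohort score
#'
#' @param sessions list of `recording_session`.
#' @param mode see [score_session()].
#' @param ... passed to [score_session()].
#' @return a `cohort_score`.
#' @export
score_cohort <- function(sessions, mode = NULL, ...) {
  cohort_score(lapply(sessions, score_session, mode = mode, ...))
}
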