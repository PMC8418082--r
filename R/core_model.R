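# Time conventions shared by every pipeline stage:
#   * timestamps are numeric seconds on the UTC timeline (POSIX seconds);
#   * intervals are half-open [start, end), so a boundary alarm at `end`
#     belongs to the next interval and is never double-counted;
#   * durations are kept in seconds and converted to hours only at the
#     reporting boundary.

#' Parse timestamps to numeric UTC seconds
#'
#' Accepts numeric seconds (returned unchanged), `POSIXct`, or ISO-8601
#' strings such as `"2021-03-01T22:15:00Z"`. All parsing is done in UTC.
#'
#' @param x numeric, `POSIXct`, or character vector.
#' @return numeric vector of seconds since the epoch.
#' @export
parse_utc <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (inherits(x, "POSIXt")) return(as.numeric(x))
  x <- sub("Z$", "", as.character(x))
  t <- as.POSIXct(x, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                 "%Y-%m-%d"))
  if (anyNA(t) && !anyNA(x)) stop("unparseable timestamp(s): ", x[is.na(t)][1])
  as.numeric(t)
}

#' Format numeric UTC seconds as ISO-8601
#'
#' Fractional seconds are kept to microsecond precision so that a
#' write/read round trip preserves timestamps.
#'
#' @param x numeric seconds.
#' @return character vector of ISO-8601 UTC strings.
#' @export
format_utc <- function(x) {
  op <- options(digits.secs = 6, OutDec = ".")
  on.exit(options(op))
  t <- as.POSIXct(x, origin = "1970-01-01", tz = "UTC")
  out <- format(t, "%Y-%m-%dT%H:%M:%OS6", tz = "UTC")
  paste0(out, "Z")
}

#' Build a validated interval table
#'
#' @param start,end vectors accepted by [parse_utc()]. Each interval is
#'   half-open `[start, end)` and must have `end > start`.
#' @param disjoint require the intervals to be pairwise disjoint.
#' @return a `data.frame` with numeric columns `start`, `end`, sorted by
#'   `start`.
#' @export
intervals <- function(start, end, disjoint = FALSE) {
  start <- parse_utc(start); end <- parse_utc(end)
  if (length(start) != length(end)) stop("start and end lengths differ")
  if (any(end <= start)) stop("interval end must exceed start")
  o <- order(start)
  out <- data.frame(start = start[o], end = end[o])
  if (disjoint && nrow(out) > 1L &&
      any(out$start[-1L] < out$end[-nrow(out)])) {
    stop("intervals overlap")
  }
  out
}

as_intervals <- function(x, disjoint = FALSE) {
  if (is.data.frame(x)) return(intervals(x$start, x$end, disjoint = disjoint))
  if (is.list(x) && !is.null(x$start)) {
    return(intervals(x$start, x$end, disjoint = disjoint))
  }
  stop("cannot interpret as intervals")
}

interval_hours <- function(iv) sum(iv$end - iv$start) / 3600

#' Is a time point inside any interval?
#'
#' Membership uses the half-open convention: `start <= t < end`.
#'
#' @param t numeric seconds.
#' @param iv interval table from [intervals()].
#' @return logical vector along `t`.
#' @export
in_intervals <- function(t, iv) {
  if (nrow(iv) == 0L) return(rep(FALSE, length(t)))
  vapply(t, function(ti) any(ti >= iv$start & ti < iv$end), logical(1))
}

#' Intersect two interval sets
#'
#' @param a,b interval tables.
#' @return interval table of all non-empty pairwise intersections.
#' @export
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  out <- list()
  for (i in seq_len(nrow(a))) {
    s <- pmax(a$start[i], b$start)
    e <- pmin(a$end[i], b$end)
    keep <- e > s
    if (any(keep)) out[[length(out) + 1L]] <- data.frame(start = s[keep], end = e[keep])
  }
  if (!length(out)) return(data.frame(start = numeric(0), end = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Complement of an interval set within a reference set
#'
#' @param iv interval table to remove.
#' @param within reference interval table (e.g. wear intervals).
#' @return intervals of `within` not covered by `iv`.
#' @export
setdiff_intervals <- function(within, iv) {
  if (nrow(iv) == 0L) return(within)
  out <- list()
  for (i in seq_len(nrow(within))) {
    cur_s <- within$start[i]; w_end <- within$end[i]
    sub <- iv[iv$end > cur_s & iv$start < w_end, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      if (sub$start[j] > cur_s) {
        out[[length(out) + 1L]] <- data.frame(start = cur_s, end = sub$start[j])
      }
      cur_s <- max(cur_s, sub$end[j])
    }
    if (cur_s < w_end) out[[length(out) + 1L]] <- data.frame(start = cur_s, end = w_end)
  }
  if (!length(out)) return(data.frame(start = numeric(0), end = numeric(0)))
  do.call(rbind, out)
}

#' Derive the study age group
#'
#' The indicated population starts at age 6; ages 6--20 (inclusive) are
#' pediatric and ages 21 and up are adult.
#'
#' @param age_years integer age(s) at enrollment.
#' @return character vector, `"pediatric"` or `"adult"`.
#' @export
derive_age_group <- function(age_years) {
  if (any(age_years < 6)) {
    stop("age below 6 is outside the device's indications for use")
  }
  ifelse(age_years <= 20, "pediatric", "adult")
}

#' Seizure types counted as convulsive
#' @export
CS_TYPES <- c("GTC", "FBTC")

#' Construct a recording session
#'
#' One patient's monitored period: wear intervals (exposure), consensus
#' seizures, and device alarms. Alarms must fall inside wear intervals;
#' offending rows raise an error at construction rather than being
#' silently dropped.
#'
#' @param patient_id identifier.
#' @param age_years integer age at enrollment (>= 6).
#' @param device `"E4"` or `"EMBRACE"`.
#' @param wear_intervals interval table (pairwise disjoint).
#' @param alarms `data.frame` with columns `time` (seconds or ISO-8601) and
#'   `mode` (`"FDA_CLEARED"` or `"ACTIVE"`), or `NULL`.
#' @param seizures `data.frame` with columns `onset`, `offset`,
#'   `type` (`"GTC"`/`"FBTC"`), `n_supporting`, or `NULL`.
#' @param sex optional.
#' @return object of class `recording_session`.
#' @export
recording_session <- function(patient_id, age_years,
                              device = c("E4", "EMBRACE"),
                              wear_intervals,
                              alarms = NULL, seizures = NULL,
                              sex = NA_character_) {
  device <- match.arg(device)
  age_group <- derive_age_group(age_years)
  wear <- as_intervals(wear_intervals, disjoint = TRUE)
  if (interval_hours(wear) <= 0) stop("session has no wear time")

  if (is.null(alarms) || nrow(alarms) == 0L) {
    alarms <- data.frame(time = numeric(0), mode = character(0))
  } else {
    alarms <- data.frame(time = parse_utc(alarms$time),
                         mode = as.character(alarms$mode))
    bad <- !in_intervals(alarms$time, wear)
    if (any(bad)) {
      stop(sprintf("%d alarm(s) outside wear intervals for patient %s",
                   sum(bad), patient_id))
    }
    alarms <- alarms[order(alarms$time), , drop = FALSE]
    rownames(alarms) <- NULL
  }

  if (is.null(seizures) || nrow(seizures) == 0L) {
    seizures <- data.frame(onset = numeric(0), offset = numeric(0),
                           type = character(0), n_supporting = integer(0))
  } else {
    seizures <- data.frame(onset = parse_utc(seizures$onset),
                           offset = parse_utc(seizures$offset),
                           type = as.character(seizures$type),
                           n_supporting = if (is.null(seizures$n_supporting))
                             rep(3L, nrow(seizures)) else as.integer(seizures$n_supporting))
    if (any(seizures$offset <= seizures$onset)) stop("seizure offset must exceed onset")
    if (!all(seizures$type %in% CS_TYPES)) {
      stop("consensus seizures must be GTC or FBTC")
    }
    if (any(seizures$n_supporting < 2L)) stop("consensus requires >= 2 supporting reviewers")
    seizures <- seizures[order(seizures$onset), , drop = FALSE]
    rownames(seizures) <- NULL
  }

  structure(list(patient_id = as.character(patient_id),
                 age_years = as.integer(age_years),
                 age_group = age_group,
                 sex = sex,
                 device = device,
                 wear_intervals = wear,
                 alarms = alarms,
                 seizures = seizures),
            class = "recording_session")
}

#' Total worn hours of a session
#'
#' @param session a `recording_session`.
#' @return hours of wear (sum of wear-interval durations).
#' @export
total_hours <- function(session) {
  stopifnot(inherits(session, "recording_session"))
  interval_hours(session$wear_intervals)
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("<recording_session %s> %s, %s, %.1f h worn, %d seizure(s), %d alarm(s)\n",
              x$patient_id, x$age_group, x$device, total_hours(x),
              nrow(x$seizures), nrow(x$alarms)))
  invisible(x)
}

#' Named operating point of the decision rule
#'
#' The device ships with two configurations: a more sensitive
#' `FDA_CLEARED` point (lower probability threshold) and a more specific
#' `ACTIVE` point (higher threshold, fewer false alarms).
#'
#' @param name `"FDA_CLEARED"` or `"ACTIVE"`.
#' @param threshold decision probability threshold in (0, 1).
#' @return object of class `operating_point`.
#' @export
operating_point <- function(name = c("FDA_CLEARED", "ACTIVE"), threshold) {
  name <- match.arg(name)
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  structure(list(name = name, threshold = threshold), class = "operating_point")
}

# ---- interchange IO ---------------------------------------------------------

#' Write / read sessions as JSON
#'
#' One record per session; interval endpoints and alarm times are stored
#' as ISO-8601 UTC strings. `read_sessions()` reconstructs
#' `recording_session` objects (revalidating all invariants).
#'
#' @param sessions list of `recording_session`.
#' @param path file path.
#' @return `write_sessions()` returns `path` invisibly; `read_sessions()`
#'   returns a list of sessions.
#' @export
write_sessions <- function(sessions, path) {
  recs <- lapply(sessions, function(s) {
    list(patient_id = s$patient_id,
         age_years = s$age_years,
         sex = s$sex,
         device = s$device,
         wear_intervals = data.frame(start = format_utc(s$wear_intervals$start),
                                     end = format_utc(s$wear_intervals$end)),
         alarms = if (nrow(s$alarms)) data.frame(time = format_utc(s$alarms$time),
                                                 mode = s$alarms$mode) else NULL,
         seizures = if (nrow(s$seizures))
           data.frame(onset = format_utc(s$seizures$onset),
                      offset = format_utc(s$seizures$offset),
                      type = s$seizures$type,
                      n_supporting = s$seizures$n_supporting) else NULL)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_df <- function(x) {
    # list of records -> data.frame with one column per field
    if (is.null(x) || !length(x)) return(NULL)
    cols <- names(x[[1]])
    out <- lapply(cols, function(cl) unlist(lapply(x, `[[`, cl)))
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  lapply(recs, function(r) {
    recording_session(patient_id = r$patient_id,
                      age_years = r$age_years,
                      device = r$device,
                      wear_intervals = as_df(r$wear_intervals),
                      alarms = as_df(r$alarms),
                      seizures = as_df(r$seizures),
                      sex = if (is.null(r$sex) || is.na(r$sex)) NA_character_
                            else r$sex)
  })
}

#' Read reviewer annotations from CSV
#'
#' Expected columns: `reviewer_id, patient_id, clinical_onset,
#' clinical_offset, eeg_onset, eeg_offset, seizure_type, pges_s` (the EEG
#' and PGES columns may be empty). Times may be ISO-8601 or numeric
#' seconds.
#'
#' @param path CSV path.
#' @return `data.frame` with numeric `onset`/`offset` columns plus the
#'   identifiers and type.
#' @export
read_annotations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("reviewer_id", "patient_id", "clinical_onset", "clinical_offset",
            "seizure_type")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("annotations file missing columns: ",
                         paste(miss, collapse = ", "))
  out <- data.frame(reviewer_id = as.character(d$reviewer_id),
                    patient_id = as.character(d$patient_id),
                    onset = parse_utc(d$clinical_onset),
                    offset = parse_utc(d$clinical_offset),
                    seizure_type = as.character(d$seizure_type))
  if (!is.null(d$pges_s)) {
    if (any(!is.na(d$pges_s) & d$pges_s < 0)) stop("pges_s must be >= 0")
    out$pges_s <- d$pges_s
  }
  if (!is.null(d$eeg_onset)) {
    out$eeg_onset <- suppressWarnings(parse_utc(d$eeg_onset))
    out$eeg_offset <- suppressWarnings(parse_utc(d$eeg_offset))
  }
  if (any(out$offset <= out$onset)) stop("annotation offset must exceed onset")
  out
}

#' Read device alarms from CSV
#'
#' Expected columns: `patient_id, timestamp, mode`.
#'
#' @param path CSV path.
#' @return `data.frame(patient_id, time, mode)`.
#' @export
read_alarms <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "timestamp", "mode")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("alarms file missing columns: ",
                         paste(miss, collapse = ", "))
  data.frame(patient_id = as.character(d$patient_id),
             time = parse_utc(d$timestamp),
             mode = as.character(d$mode))
}

#' Write consensus seizures to CSV
#'
#' @param consensus `data.frame` from [adjudicate()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(consensus, path) {
  out <- consensus
  out$onset <- format_utc(out$onset)
  out$offset <- format_utc(out$offset)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
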