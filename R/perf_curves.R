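# ROC / precision-recall construction for a continuous monitoring stream.
# Specificity is not directly defined for monitoring data (there is no
# natural count of "no-seizure events"), so non-seizure time is carved into
# a sequence of non-overlapping pseudo-negative events whose duration equals
# the mean duration of the consensus seizures.

#' Pseudo-negative event model
#'
#' @param total_hours total worn hours.
#' @param seizure_hours hours occupied by consensus seizures.
#' @param mean_cs_duration mean consensus-seizure duration in seconds
#'   (> 0).
#' @return list `n_negative_events` (`floor(non-seizure seconds /
#'   duration)`) and `mean_event_duration`; a `flag` is set when no whole
#'   negative event fits (specificity undefined).
#' @export
pseudo_negatives <- function(total_hours, seizure_hours, mean_cs_duration) {
  stopifnot(total_hours >= seizure_hours, seizure_hours >= 0)
  if (mean_cs_duration <= 0) stop("mean_cs_duration must be positive")
  n <- floor((total_hours - seizure_hours) * 3600 / mean_cs_duration)
  list(n_negative_events = n,
       mean_event_duration = mean_cs_duration,
       flag = if (n == 0) "no_negative_events" else NULL)
}

#' Sweep a detector over a threshold grid
#'
#' @param count_fn function of one threshold returning a list or named
#'   vector with elements `detected` and `false_alarms` (counts at that
#'   threshold).
#' @param thresholds strictly increasing probability grid (default 101
#'   evenly spaced levels).
#' @param n_events number of consensus seizures.
#' @param hours total worn hours.
#' @param n_negatives pseudo-negative event count from
#'   [pseudo_negatives()].
#' @param confidence per-point confidence level (Wilson for proportions,
#'   normal approximation for the FAR).
#' @return `data.frame` with one row per threshold: counts, sensitivity,
#'   specificity, precision, FAR and their interval bounds.
#' @export
sweep_thresholds <- function(count_fn, thresholds = seq(0, 1, length.out = 101),
                             n_events, hours, n_negatives,
                             confidence = 0.95) {
  if (!length(thresholds)) stop("empty threshold grid")
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  stopifnot(n_events >= 1, hours > 0, n_negatives >= 0)
  rows <- lapply(thresholds, function(th) {
    ct <- count_fn(th)
    det <- as.numeric(ct[["detected"]])
    fa <- as.numeric(ct[["false_alarms"]])
    sens <- wilson(det, n_events, confidence)
    spec <- if (n_negatives > 0) wilson(n_negatives - min(fa, n_negatives),
                                        n_negatives, confidence) else NULL
    farci <- far_normal_ci(fa, hours, confidence)
    data.frame(threshold = th, n_detected = det, n_false_alarms = fa,
               sensitivity = det / n_events,
               sens_lower = sens$lower, sens_upper = sens$upper,
               specificity = if (is.null(spec)) NA_real_
                             else 1 - min(fa, n_negatives) / n_negatives,
               spec_lower = if (is.null(spec)) NA_real_ else spec$lower,
               spec_upper = if (is.null(spec)) NA_real_ else spec$upper,
               precision = if (det + fa > 0) det / (det + fa) else NA_real_,
               far = farci$estimate, far_lower = farci$lower,
               far_upper = farci$upper)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Precision-recall curve from a threshold sweep
#'
#' Recall is the sensitivity; precision is `TP / (TP + FA)` at each
#' threshold. Thresholds producing no alerts have undefined precision and
#' are dropped (their count is reported in the `"dropped"` attribute).
#'
#' @param points `data.frame` from [sweep_thresholds()].
#' @return `data.frame(threshold, recall, precision)`.
#' @export
pr_curve <- function(points) {
  keep <- !is.na(points$precision)
  out <- data.frame(threshold = points$threshold[keep],
                    recall = points$sensitivity[keep],
                    precision = points$precision[keep])
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Build a threshold-count function from window scores
#'
#' Convenience for sweeping: given the maximum detector score inside each
#' consensus seizure and the scores of candidate false-alarm episodes
#' (non-seizure supra-baseline excursions), counts detections and false
#' alarms at any threshold.
#'
#' @param event_scores numeric, one max score per consensus seizure.
#' @param background_scores numeric, one score per non-seizure episode.
#' @return function usable as `count_fn` in [sweep_thresholds()].
#' @export
make_count_fn <- function(event_scores, background_scores) {
  force(event_scores); force(background_scores)
  function(th) list(detected = sum(event_scores >= th),
                    false_alarms = sum(background_scores >= th))
}
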