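# Actigraphy rest detection. The magnitude of the tri-axial wrist
# accelerometer is band-pass filtered; activity counts are the number of
# upward crossings of the filtered magnitude through a small threshold,
# accumulated over 30-s epochs; rest begins when a 30-min moving average of
# the counts falls below a count threshold and ends when it rises above;
# rest periods less than 2 h apart are merged (assumed rest interruptions).
# Detected rest is a proxy for sleep and is used to stratify performance.

#' Rest-detection configuration
#'
#' The band corners, crossing threshold and count threshold are not fixed
#' by any standard; defaults were chosen so that low-motion sleep in the
#' synthetic signal generator is recovered, and all are tunable.
#'
#' @param epoch_length epoch length in seconds (default 30).
#' @param smoothing_window moving-average window in minutes (default 30).
#' @param merge_gap rest periods closer than this many hours are merged
#'   (default 2).
#' @param bandpass band-pass corner frequencies in Hz (default 0.25--3).
#' @param crossing_threshold acceleration threshold in g for an upward
#'   crossing (default 0.02).
#' @param rest_count_threshold counts-per-epoch level below which the
#'   smoothed activity is rest (default 10).
#' @return a `rest_config` list.
#' @export
rest_config <- function(epoch_length = 30, smoothing_window = 30,
                        merge_gap = 2, bandpass = c(0.25, 3),
                        crossing_threshold = 0.02,
                        rest_count_threshold = 10) {
  stopifnot(epoch_length > 0, smoothing_window > 0, merge_gap > 0,
            length(bandpass) == 2, bandpass[1] < bandpass[2],
            crossing_threshold > 0, rest_count_threshold > 0)
  structure(list(epoch_length = epoch_length,
                 smoothing_window = smoothing_window,
                 merge_gap = merge_gap,
                 bandpass = bandpass,
                 crossing_threshold = crossing_threshold,
                 rest_count_threshold = rest_count_threshold),
            class = "rest_config")
}

#' Per-epoch activity counts from tri-axial accelerometry
#'
#' The vector magnitude is band-pass filtered (zero-phase Butterworth, to
#' avoid biasing rest onset/offset timing) and the count of upward
#' crossings through `crossing_threshold` is accumulated per epoch.
#'
#' @param acm `data.frame(t, x, y, z)`: time in seconds (uniform 32 Hz by
#'   default) and acceleration in g.
#' @param config a [rest_config()].
#' @param fs sampling frequency in Hz (default 32).
#' @return `data.frame(epoch_start, counts)`; trailing samples not
#'   filling a whole epoch are discarded.
#' @export
activity_counts <- function(acm, config = rest_config(), fs = 32) {
  stopifnot(all(c("t", "x", "y", "z") %in% names(acm)))
  dt <- diff(acm$t)
  if (length(dt) && (max(dt) - min(dt)) > 0.5 / fs) {
    stop("non-uniform sampling in accelerometer record")
  }
  mag <- sqrt(acm$x^2 + acm$y^2 + acm$z^2)
  ny <- fs / 2
  bf <- signal::butter(2, config$bandpass / ny, type = "pass")
  filt <- signal::filtfilt(bf, mag - mean(mag))
  thr <- config$crossing_threshold
  up <- c(FALSE, filt[-1] >= thr & filt[-length(filt)] < thr)
  per_epoch <- as.integer(round(config$epoch_length * fs))
  n_epochs <- floor(length(filt) / per_epoch)
  if (n_epochs < 1) stop("less than one epoch of data")
  idx <- rep(seq_len(n_epochs), each = per_epoch)
  counts <- as.vector(tapply(up[seq_len(n_epochs * per_epoch)], idx, sum))
  data.frame(epoch_start = acm$t[1] + (seq_len(n_epochs) - 1) * config$epoch_length,
             counts = as.numeric(counts))
}

#' Detect rest intervals from per-epoch activity counts
#'
#' A centered moving average over `smoothing_window` minutes of counts is
#' thresholded at `rest_count_threshold`: rest starts when the average
#' falls below and ends when it rises to or above the threshold.
#' Resulting rest periods separated by less than `merge_gap` hours are
#' merged.
#'
#' @param counts `data.frame(epoch_start, counts)` from
#'   [activity_counts()]; `NA` counts (missing epochs) are treated as
#'   active.
#' @param config a [rest_config()].
#' @return `data.frame(start, end, mean_counts)`, sorted and disjoint;
#'   zero rows (with a warning) if all counts are missing.
#' @export
detect_rest <- function(counts, config = rest_config()) {
  ep <- config$epoch_length
  x <- counts$counts
  if (all(is.na(x))) {
    warning("all activity counts missing")
    return(data.frame(start = numeric(0), end = numeric(0),
                      mean_counts = numeric(0)))
  }
  w <- max(1L, as.integer(round(config$smoothing_window * 60 / ep)))
  if (w %% 2L == 0L) w <- w + 1L
  xa <- x; xa[is.na(xa)] <- Inf        # missing epochs never count as rest
  sm <- stats::filter(xa, rep(1 / w, w), sides = 2)
  sm <- as.numeric(sm)
  # shrink the window at the record edges rather than dropping them
  half <- (w - 1L) / 2L
  n <- length(xa)
  for (i in which(is.na(sm))) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    sm[i] <- mean(xa[lo:hi])
  }
  rest <- sm < config$rest_count_threshold
  r <- rle(rest)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(start = counts$epoch_start[starts[r$values]],
                   end = counts$epoch_start[ends[r$values]] + ep)
  if (!nrow(iv)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      mean_counts = numeric(0)))
  }
  iv <- iv[order(iv$start), , drop = FALSE]
  # merge rest periods separated by less than merge_gap hours
  gap <- config$merge_gap * 3600
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] - merged$end[nrow(merged)] < gap) {
      merged$end[nrow(merged)] <- iv$end[i]
    } else {
      merged <- rbind(merged, iv[i, ])
    }
  }
  merged$mean_counts <- vapply(seq_len(nrow(merged)), function(i) {
    sel <- counts$epoch_start >= merged$start[i] &
      counts$epoch_start < merged$end[i]
    mean(x[sel], na.rm = TRUE)
  }, numeric(1))
  rownames(merged) <- NULL
  merged
}

#' Cohort summary of detected rest
#'
#' @param rest_list list of rest-interval tables, one per session.
#' @param wear_hours numeric vector of worn hours per session.
#' @return list `total_hours`, `fraction_of_wear`, `median_duration`
#'   (hours; `NA` with `flag` when no rest), and
#'   `median_periods_per_day` (median over sessions of rest periods per
#'   24 h worn).
#' @export
rest_summary <- function(rest_list, wear_hours) {
  stopifnot(length(rest_list) == length(wear_hours))
  durs <- unlist(lapply(rest_list, function(iv)
    if (is.null(iv) || !nrow(iv)) numeric(0) else (iv$end - iv$start) / 3600))
  per_day <- vapply(seq_along(rest_list), function(i) {
    n <- if (is.null(rest_list[[i]])) 0L else nrow(rest_list[[i]])
    n / (wear_hours[i] / 24)
  }, numeric(1))
  tot <- sum(durs)
  list(total_hours = tot,
       fraction_of_wear = tot / sum(wear_hours),
       median_duration = if (length(durs)) stats::median(durs) else NA_real_,
       median_periods_per_day = stats::median(per_day),
       flag = if (!length(durs)) "no_rest" else NULL)
}
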