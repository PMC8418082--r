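# Transparent surrogate detector. The commercial detection algorithm (a
# pre-trained classifier over 40 proprietary ACM/EDA features) is not
# public; this module implements only its published architecture --
# consecutive 10-s windows overlapped by 75%, a per-window seizure
# probability, and a thresholded decision rule with two named operating
# points -- with a transparent logistic score in place of the trained
# model, so the evaluation pipeline can be exercised end to end. It makes
# no claim to reproduce the commercial algorithm's performance.

#' Surrogate detector configuration
#'
#' @param window_length analysis window in seconds (default 10).
#' @param overlap_fraction fractional overlap of consecutive windows
#'   (default 0.75, i.e. a 2.5-s stride).
#' @param threshold_fda decision threshold of the more sensitive
#'   FDA-cleared-style operating point.
#' @param threshold_active decision threshold of the more specific Active
#'   operating point; must exceed `threshold_fda`.
#' @param refractory seconds after an alarm during which further alarms
#'   are suppressed (default 180), preventing one seizure from producing
#'   an alarm train.
#' @return a `detector_config` list.
#' @export
detector_config <- function(window_length = 10, overlap_fraction = 0.75,
                            threshold_fda = 0.35, threshold_active = 0.65,
                            refractory = 180) {
  stopifnot(window_length > 0, overlap_fraction >= 0, overlap_fraction < 1,
            threshold_fda > 0, threshold_active < 1,
            threshold_fda < threshold_active, refractory >= 0)
  structure(list(window_length = window_length,
                 overlap_fraction = overlap_fraction,
                 threshold_fda = threshold_fda,
                 threshold_active = threshold_active,
                 refractory = refractory),
            class = "detector_config")
}

#' Analysis windows over a signal
#'
#' Stride is `window_length * (1 - overlap_fraction)`; the window count
#' is `floor((duration - window) / stride) + 1`.
#'
#' @param signal_duration total signal duration in seconds.
#' @param config a [detector_config()].
#' @return `data.frame(start, end)`; zero rows (with attribute
#'   `flag = "too_short"`) when the signal is shorter than one window.
#' @export
detector_windows <- function(signal_duration, config = detector_config()) {
  wl <- config$window_length
  if (signal_duration < wl) {
    out <- data.frame(start = numeric(0), end = numeric(0))
    attr(out, "flag") <- "too_short"
    return(out)
  }
  stride <- wl * (1 - config$overlap_fraction)
  n <- floor((signal_duration - wl) / stride) + 1
  start <- (seq_len(n) - 1) * stride
  data.frame(start = start, end = start + wl)
}

# coefficient set of the logistic surrogate score; fixed constants of the
# surrogate, not tunable operating parameters.
.surrogate_coefs <- c(intercept = -8, clonic = 2.2, rhythm = 3.0,
                      eda_level = 0.6, eda_slope = 4.0)

#' Rhythmicity of an oscillatory window
#'
#' Regularity of the intervals between successive upward crossings of the
#' detrended signal through its own RMS level: `1 / (1 + cv)` where `cv`
#' is the coefficient of variation of the crossing intervals. A sustained
#' clonic oscillation gives values near 1; diffuse movement with the same
#' energy (or a phase-scrambled version of the burst) crosses its RMS
#' irregularly and scores lower. Returns 0 with fewer than four
#' crossings.
#'
#' @param x numeric signal (one window of detrended ACM magnitude).
#' @return rhythmicity in \[0, 1\].
#' @export
rhythmicity <- function(x) {
  xd <- x - mean(x)
  thr <- stats::sd(xd)
  if (!is.finite(thr) || thr == 0) return(0)
  up <- which(xd[-1] >= thr & xd[-length(xd)] < thr)
  if (length(up) < 4) return(0)
  iv <- diff(up)
  cv <- stats::sd(iv) / mean(iv)
  1 / (1 + cv)
}

# band power of the detrended signal in [lo, hi] Hz via the periodogram
band_power <- function(x, fs, lo, hi) {
  xd <- x - mean(x)
  n <- length(xd)
  sp <- Mod(stats::fft(xd))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- freqs >= lo & freqs <= hi
  sum(sp[sel]) / n
}

#' Surrogate per-window seizure score
#'
#' Logistic combination of transparent features: band-limited ACM energy
#' in the clonic band (2--6 Hz), rhythmicity of the oscillation, EDA
#' level and EDA slope. Monotone increasing in the clonic-band energy.
#'
#' @param acm numeric vector, ACM magnitude over one window (g).
#' @param eda numeric vector, EDA over the same window (microsiemens).
#' @param fs_acm,fs_eda sampling frequencies in Hz.
#' @return probability in (0, 1), or `NA` when either modality is
#'   missing/empty (score withheld).
#' @export
window_score <- function(acm, eda, fs_acm = 32, fs_eda = 4) {
  if (!length(acm) || !length(eda) || anyNA(acm) || anyNA(eda)) {
    return(NA_real_)
  }
  cl <- band_power(acm, fs_acm, 2, 6)
  rh <- rhythmicity(acm)
  lev <- mean(eda)
  slope <- (eda[length(eda)] - eda[1]) / (length(eda) / fs_eda)
  b <- .surrogate_coefs
  stats::plogis(b["intercept"] + b["clonic"] * log1p(100 * cl) +
                  b["rhythm"] * rh + b["eda_level"] * log1p(lev) +
                  b["eda_slope"] * max(0, slope))[[1]]
}

#' Decision rule: threshold window scores into alarms
#'
#' An alarm is raised at the first window whose score meets the
#' threshold; subsequent supra-threshold windows inside the refractory
#' period are suppressed. Raising the threshold can only remove
#' supra-threshold windows, so Active-mode alarm and detection counts
#' never exceed FDA-mode counts on the same scores.
#'
#' @param scores `data.frame(time, score)`, time-ordered window scores
#'   (`time` = window start, seconds). `NA` scores are skipped.
#' @param threshold decision threshold in (0, 1), or an
#'   [operating_point()].
#' @param config a [detector_config()] (for the refractory period).
#' @return numeric vector of alarm times (possibly empty).
#' @export
decide <- function(scores, threshold, config = detector_config()) {
  if (inherits(threshold, "operating_point")) threshold <- threshold$threshold
  if (is.unsorted(scores$time)) stop("scores must be time-ordered")
  alarms <- numeric(0)
  last <- -Inf
  for (i in seq_len(nrow(scores))) {
    s <- scores$score[i]
    if (is.na(s) || s < threshold) next
    if (scores$time[i] - last >= config$refractory) {
      alarms <- c(alarms, scores$time[i])
      last <- scores$time[i]
    }
  }
  alarms
}

#' Run the surrogate detector over a recording
#'
#' Windows the ACM magnitude and EDA streams, scores each window, and
#' applies the decision rule at both operating points.
#'
#' @param acm `data.frame(t, x, y, z)` at `fs_acm` Hz.
#' @param eda `data.frame(t, eda)` at `fs_eda` Hz.
#' @param config a [detector_config()].
#' @param fs_acm,fs_eda sampling frequencies.
#' @return list `scores` (`data.frame(time, score)`), `alarms_fda`,
#'   `alarms_active` (alarm-time vectors).
#' @export
detect_alarms <- function(acm, eda, config = detector_config(),
                          fs_acm = 32, fs_eda = 4) {
  t0 <- acm$t[1]
  dur <- acm$t[nrow(acm)] - t0 + 1 / fs_acm
  win <- detector_windows(dur, config)
  mag <- sqrt(acm$x^2 + acm$y^2 + acm$z^2)
  na <- nrow(acm); ne <- nrow(eda)
  scores <- vapply(seq_len(nrow(win)), function(i) {
    # uniform sampling: index windows arithmetically
    ia0 <- floor(win$start[i] * fs_acm) + 1L
    ia1 <- min(na, ia0 + as.integer(config$window_length * fs_acm) - 1L)
    ie0 <- floor(win$start[i] * fs_eda) + 1L
    ie1 <- min(ne, ie0 + as.integer(config$window_length * fs_eda) - 1L)
    window_score(mag[ia0:ia1], eda$eda[ie0:ie1], fs_acm, fs_eda)
  }, numeric(1))
  sc <- data.frame(time = t0 + win$start, score = scores)
  list(scores = sc,
       alarms_fda = decide(sc, config$threshold_fda, config),
       alarms_active = decide(sc, config$threshold_active, config))
}
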