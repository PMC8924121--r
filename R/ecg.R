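# Recording container ---------------------------------------------------------

#' Construct a uniformly sampled physiological recording
#'
#' Lightweight container for one channel (ECG in mV or skin conductance in
#' µS) sampled uniformly at `fs` Hz, starting at time `t0` seconds.
#'
#' @param samples Numeric vector of finite sample values.
#' @param fs Sampling frequency in Hz (> 0).
#' @param channel `"ecg"` or `"gsr"`.
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `recording`.
#' @export
new_recording <- function(samples, fs, channel = c("ecg", "gsr"), t0 = 0) {
  channel <- match.arg(channel)
  stopifnot(is.numeric(samples), length(samples) > 0, fs > 0)
  if (!all(is.finite(samples))) stop("recording contains non-finite samples")
  structure(list(samples = as.numeric(samples), fs = fs,
                 channel = channel, t0 = t0),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording: %s, %d samples @ %g Hz, %.1f s>\n",
              x$channel, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Sample times of a recording
#' @param rec A `recording`.
#' @return Numeric vector of times in seconds.
#' @export
recording_times <- function(rec) {
  rec$t0 + (seq_along(rec$samples) - 1) / rec$fs
}

# ECG cleaning -----------------------------------------------------------------

#' Trimmed moving-average filter
#'
#' Replaces each sample by the trimmed mean of its centred window: the
#' `floor(trim_frac * W)` smallest and largest values of the window are
#' discarded before averaging. This suppresses brief high-amplitude muscle
#' artifacts while tracking the baseline. Windows are truncated (never
#' padded) at the signal edges.
#'
#' @param rec A `recording`.
#' @param window_s Window length in seconds (default 0.2 s).
#' @param trim_frac Fraction trimmed from each tail, in `[0, 0.5)`
#'   (default 0.25).
#' @return A filtered `recording` of the same length.
#' @export
trimmed_moving_average <- function(rec, window_s = 0.2, trim_frac = 0.25) {
  stopifnot(inherits(rec, "recording"))
  if (trim_frac < 0 || trim_frac >= 0.5)
    stop("trim_frac must be in [0, 0.5)")
  w <- round(window_s * rec$fs)
  if (w < 3) stop("window must span at least 3 samples")
  if (w > length(rec$samples)) stop("window longer than the signal")
  left <- (w - 1L) %/% 2L
  right <- w - 1L - left
  out <- .trimmed_running_mean_cpp(rec$samples, as.integer(left),
                                   as.integer(right), trim_frac)
  new_recording(out, rec$fs, rec$channel, rec$t0)
}

#' Z-score a recording
#'
#' Centres to mean 0 and scales to unit sample standard deviation.
#'
#' @param rec A `recording`.
#' @return A standardized `recording`.
#' @export
zscore_signal <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  s <- sd(rec$samples)
  if (!is.finite(s) || s == 0) stop("cannot z-score a zero-variance signal")
  new_recording((rec$samples - mean(rec$samples)) / s,
                rec$fs, rec$channel, rec$t0)
}

#' Detect R peaks in a filtered, z-scored ECG
#'
#' Local-maxima detection with an adaptive prominence threshold (a fraction
#' of the 99th-percentile amplitude) and a refractory period equal to the RR
#' interval of the fastest physiologically valid heart rate (220 bpm). When
#' two candidate peaks fall inside one refractory period the larger is kept.
#'
#' @param rec A z-scored, filtered ECG `recording`.
#' @param threshold_frac Prominence threshold as a fraction of the
#'   99th-percentile amplitude (default 0.5).
#' @return Strictly increasing R-peak times in seconds (possibly empty, with
#'   a warning, when no peak clears the threshold).
#' @export
detect_beats <- function(rec, threshold_frac = 0.5) {
  stopifnot(inherits(rec, "recording"))
  x <- rec$samples
  n <- length(x)
  if (n < 3) {
    warning("signal too short for beat detection")
    return(numeric(0))
  }
  thr <- threshold_frac * quantile(x, 0.99, names = FALSE)
  core <- x[2:(n - 1)]
  is_peak <- core > x[1:(n - 2)] & core >= x[3:n] & core > thr
  idx <- which(is_peak) + 1L
  if (length(idx) == 0) {
    warning("no R peaks found")
    return(numeric(0))
  }
  refractory_s <- .RR_MIN_MS / 1000
  # greedy by amplitude: a peak is kept unless a larger accepted peak is
  # within the refractory period
  ord <- idx[order(x[idx], decreasing = TRUE)]
  keep <- logical(0)
  kept_t <- numeric(0)
  for (i in ord) {
    t_i <- (i - 1) / rec$fs
    if (all(abs(kept_t - t_i) >= refractory_s)) kept_t <- c(kept_t, t_i)
  }
  sort(kept_t) + rec$t0
}

# RR series --------------------------------------------------------------------

#' Build an RR-interval series from R-peak times
#'
#' Successive differences of the R times give the RR intervals in ms; each
#' interval is marked valid when it lies in the 50--220 bpm band.
#'
#' @param r_times Strictly increasing R-peak times (s).
#' @return A `beat_series` list with `r_times`, `rr_ms`, `valid_mask`, and
#'   (initially `NULL`) `rrr` / `artifact_mask`. Fewer than 2 beats yields an
#'   empty series flagged `missing`.
#' @export
compute_rr <- function(r_times) {
  if (length(r_times) >= 2 && any(diff(r_times) <= 0))
    stop("r_times must be strictly increasing")
  if (length(r_times) < 2) {
    out <- structure(list(r_times = r_times, rr_ms = numeric(0),
                          valid_mask = logical(0), rrr = NULL,
                          artifact_mask = NULL),
                     class = "beat_series")
    attr(out, "missing") <- TRUE
    return(out)
  }
  rr <- diff(r_times) * 1000
  structure(list(r_times = r_times, rr_ms = rr,
                 valid_mask = rr >= .RR_MIN_MS & rr <= .RR_MAX_MS,
                 rrr = NULL, artifact_mask = NULL),
            class = "beat_series")
}

#' Relative RR intervals
#'
#' The normalized successive change
#' `rrr_i = 2 (RR_{i+1} - RR_i) / (RR_{i+1} + RR_i)`, a dimensionless
#' quantity in (-2, 2) used both for artifact screening and for the
#' return-map features.
#'
#' @param rr_ms RR intervals in ms (all positive, length >= 2).
#' @return Numeric vector of length `length(rr_ms) - 1`.
#' @export
relative_rr <- function(rr_ms) {
  if (any(rr_ms <= 0)) stop("RR intervals must be positive")
  if (length(rr_ms) < 2) stop("need at least 2 RR intervals")
  n <- length(rr_ms)
  2 * (rr_ms[-1] - rr_ms[-n]) / (rr_ms[-1] + rr_ms[-n])
}

#' Flag and remove RR artifacts via relative RR
#'
#' An interior RR interval is flagged as an artifact when the relative-RR
#' change on *both* of its sides exceeds `threshold` in absolute value (an
#' ectopic or missed beat perturbs both flanking transitions, whereas the
#' intervals neighbouring an artifact show only one large transition); an
#' edge interval is flagged on its single available side. Intervals outside
#' the 50--220 bpm validity band are always flagged.
#'
#' @param beats A `beat_series` from [compute_rr()].
#' @param threshold Relative-RR magnitude cutoff (default 0.2, i.e. a 20%
#'   beat-to-beat change).
#' @return The `beat_series` with `rrr`, `artifact_mask`, a `cleaned_rr`
#'   vector, and attribute `fraction_removed`. When everything is flagged
#'   the cleaned series is empty and the result carries `missing = TRUE`.
#' @export
remove_artifacts <- function(beats, threshold = 0.2) {
  stopifnot(inherits(beats, "beat_series"))
  rr <- beats$rr_ms
  n <- length(rr)
  if (n < 2) {
    beats$cleaned_rr <- rr[beats$valid_mask]
    beats$artifact_mask <- !beats$valid_mask
    attr(beats, "fraction_removed") <- if (n) mean(beats$artifact_mask) else NA_real_
    if (length(beats$cleaned_rr) == 0) attr(beats, "missing") <- TRUE
    return(beats)
  }
  rrr <- relative_rr(rr)
  big <- abs(rrr) > threshold          # big[j] : transition rr[j] -> rr[j+1]
  flag <- logical(n)
  flag[1] <- big[1]
  flag[n] <- big[n - 1]
  if (n > 2) {
    mid <- 2:(n - 1)
    flag[mid] <- big[mid - 1] & big[mid]
  }
  flag <- flag | !beats$valid_mask
  beats$rrr <- rrr
  beats$artifact_mask <- flag
  beats$cleaned_rr <- rr[!flag]
  attr(beats, "fraction_removed") <- mean(flag)
  if (length(beats$cleaned_rr) == 0) attr(beats, "missing") <- TRUE
  beats
}
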