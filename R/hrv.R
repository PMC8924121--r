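# Per-epoch HRV features ------------------------------------------------------
# All operations take a cleaned RR series (ms) for one epoch and return named
# numerics; a feature that cannot be computed is NA (flagged missing), never
# a silent NaN.

#' Time-domain HRV features
#'
#' @param rr_ms Cleaned RR intervals in ms.
#' @return Named vector `mean_rr`, `sd_rr` (sample SD), `rmssd`
#'   (`sqrt(mean(diff(rr)^2))`), `pnn50` (fraction of successive differences
#'   exceeding 50 ms). `rmssd`/`pnn50` require at least 3 intervals and are
#'   NA otherwise; `mean_rr`/`sd_rr` require 2.
#' @export
hrv_time_domain <- function(rr_ms) {
  out <- c(mean_rr = NA_real_, sd_rr = NA_real_,
           rmssd = NA_real_, pnn50 = NA_real_)
  n <- length(rr_ms)
  if (n >= 2) {
    out["mean_rr"] <- mean(rr_ms)
    out["sd_rr"] <- sd(rr_ms)
  }
  if (n >= 3) {
    d <- diff(rr_ms)
    out["rmssd"] <- sqrt(mean(d^2))
    out["pnn50"] <- mean(abs(d) > 50)
  }
  out
}

#' Return-map features of relative RR intervals
#'
#' Embeds the relative-RR series as points `(rrr_i, rrr_{i+1})`, takes the
#' Euclidean distance of each point to the centroid of the cloud, and
#' reports the median and the interquartile range ("annular intensity") of
#' those distances.
#'
#' @param rrr Relative RR intervals (dimensionless).
#' @return Named vector `rm_median`, `rm_iqr`; NA when fewer than 2
#'   return-map points are available.
#' @export
hrv_return_map <- function(rrr) {
  out <- c(rm_median = NA_real_, rm_iqr = NA_real_)
  if (length(rrr) < 3) return(out)
  x <- rrr[-length(rrr)]
  y <- rrr[-1]
  d <- sqrt((x - mean(x))^2 + (y - mean(y))^2)
  out["rm_median"] <- median(d)
  out["rm_iqr"] <- IQR(d)
  out
}

#' Geometric HRV features (TRI and TINN)
#'
#' The RR histogram uses the HRV-standard bin width of 1/128 s (7.8125 ms)
#' with bins aligned at zero. TRI is the total interval count divided by the
#' modal bin count (the reciprocal of the modal bin probability). TINN is
#' the baseline width (ms) of the triangle — apex fixed at the modal bin at
#' modal height, baseline endpoints on the bin grid — that minimizes the
#' squared error to the histogram, found by exhaustive search over endpoint
#' pairs.
#'
#' @param rr_ms Cleaned RR intervals in ms.
#' @return Named vector `tri` (>= 1), `tinn` (ms). A single-bin histogram
#'   degenerates to `tri = 1`, `tinn =` one bin width.
#' @export
hrv_geometric <- function(rr_ms) {
  out <- c(tri = NA_real_, tinn = NA_real_)
  if (length(rr_ms) < 2) return(out)
  bw <- 1000 / 128                      # 1/128 s in ms
  bin <- floor(rr_ms / bw)
  lo <- min(bin); hi <- max(bin)
  counts <- tabulate(bin - lo + 1L, nbins = hi - lo + 1L)
  out["tri"] <- length(rr_ms) / max(counts)
  if (length(counts) == 1) {
    out["tinn"] <- bw
    return(out)
  }
  # pad one empty bin on each side so the baseline can close the triangle
  counts <- c(0, counts, 0)
  centers <- (seq.int(lo - 1L, hi + 1L) + 0.5) * bw
  mode_i <- which.max(counts)
  peak <- counts[mode_i]
  nb <- length(counts)
  best <- Inf; best_n <- 1L; best_m <- nb
  for (ni in seq_len(mode_i - 1L)) {
    for (mi in seq.int(mode_i + 1L, nb)) {
      tri_fn <- numeric(nb)
      up <- ni:mode_i
      tri_fn[up] <- peak * (centers[up] - centers[ni]) /
        (centers[mode_i] - centers[ni])
      down <- mode_i:mi
      tri_fn[down] <- peak * (centers[mi] - centers[down]) /
        (centers[mi] - centers[mode_i])
      err <- sum((counts - tri_fn)^2)
      if (err < best - 1e-12) {
        best <- err; best_n <- ni; best_m <- mi
      }
    }
  }
  out["tinn"] <- centers[best_m] - centers[best_n]
  out
}

#' Poincare-plot HRV features (SD1, SD2)
#'
#' Dispersion of the RR return map perpendicular to (SD1, short-term HRV)
#' and along (SD2, long-term HRV) the identity line, as population standard
#' deviations of the rotated coordinates `(RR_{i+1} -/+ RR_i) / sqrt(2)`.
#'
#' @param rr_ms Cleaned RR intervals in ms (>= 3).
#' @return Named vector `sd1`, `sd2`, `sd1_sd2`; the ratio is NA when
#'   `sd2 = 0`.
#' @export
hrv_poincare <- function(rr_ms) {
  out <- c(sd1 = NA_real_, sd2 = NA_real_, sd1_sd2 = NA_real_)
  n <- length(rr_ms)
  if (n < 3) return(out)
  a <- rr_ms[-n]; b <- rr_ms[-1]
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  out["sd1"] <- pop_sd((b - a) / sqrt(2))
  out["sd2"] <- pop_sd((b + a) / sqrt(2))
  if (out["sd2"] > 0) out["sd1_sd2"] <- out["sd1"] / out["sd2"]
  out
}

# Welch periodogram of a uniformly sampled series; returns data.frame(f, psd)
.welch_psd <- function(x, fs, seg_len, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq.int(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))  # Hann
  norm <- fs * sum(w^2)
  nf <- seg_len %/% 2L
  acc <- numeric(nf + 1L)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg))^2 / norm
    half <- sp[seq_len(nf + 1L)]
    # fold: one-sided PSD doubles all non-DC/non-Nyquist bins
    if (nf >= 2) half[2:(nf + if (seg_len %% 2L == 0L) 0L else 1L)] <-
        2 * half[2:(nf + if (seg_len %% 2L == 0L) 0L else 1L)]
    acc <- acc + half
  }
  data.frame(f = (0:nf) * fs / seg_len, psd = acc / length(starts))
}

#' Spectral HRV features (LF, HF, LF/HF)
#'
#' The RR tachogram is interpolated with a cubic spline at 4 Hz, linearly
#' detrended, and its Welch periodogram (Hann windows of up to 60 s, 50%
#' overlap) integrated over the low-frequency band [0.04, 0.15) Hz and the
#' high-frequency band [0.15, 0.40) Hz.
#'
#' @param rr_ms Cleaned RR intervals in ms.
#' @param r_times Optional beat times (s) of the interval *ends*; defaults
#'   to the cumulative sum of `rr_ms`.
#' @return Named vector `lf`, `hf` (ms^2), `lf_hf`. Epochs shorter than 50 s
#'   carry attribute `low_confidence = TRUE`; `lf_hf` is NA when `hf = 0`.
#' @export
hrv_spectral <- function(rr_ms, r_times = NULL) {
  out <- c(lf = NA_real_, hf = NA_real_, lf_hf = NA_real_)
  if (length(rr_ms) < 8) return(out)
  if (is.null(r_times)) r_times <- cumsum(rr_ms) / 1000
  if (length(r_times) != length(rr_ms))
    r_times <- tail(r_times, length(rr_ms))
  fs_i <- 4
  span <- diff(range(r_times))
  if (span < 2) return(out)
  grid <- seq(min(r_times), max(r_times), by = 1 / fs_i)
  tach <- spline(r_times, rr_ms, xout = grid, method = "natural")$y
  # linear detrend
  tt <- seq_along(tach)
  fit <- lm.fit(cbind(1, tt), tach)
  tach <- tach - cbind(1, tt) %*% fit$coefficients
  psd <- .welch_psd(as.numeric(tach), fs_i, seg_len = min(length(tach), 60 * fs_i))
  df <- psd$f[2] - psd$f[1]
  out["lf"] <- sum(psd$psd[psd$f >= 0.04 & psd$f < 0.15]) * df
  out["hf"] <- sum(psd$psd[psd$f >= 0.15 & psd$f < 0.40]) * df
  if (out["hf"] > 0) out["lf_hf"] <- out["lf"] / out["hf"]
  if (span < 50) attr(out, "low_confidence") <- TRUE
  out
}

#' Approximate entropy of an RR series
#'
#' ApEn(m, r) in the standard formulation with self-matches included:
#' `phi_m - phi_{m+1}`, where `phi_m` is the mean log fraction of template
#' pairs of length `m` within Chebyshev distance `r`. The tolerance is
#' `r_frac` times the sample SD of the series.
#'
#' @param x Numeric series (RR intervals in ms).
#' @param m Embedding dimension (default 2).
#' @param r_frac Tolerance as a fraction of the series SD (default 0.2).
#' @return Nonnegative scalar; 0 by convention for a constant series.
#' @export
approximate_entropy <- function(x, m = 2, r_frac = 0.2) {
  n <- length(x)
  if (n < m + 2) return(NA_real_)
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(0)
  r <- r_frac * s
  phi <- function(mm) {
    nt <- n - mm + 1L
    # Chebyshev distances between all template pairs, built up per lag
    dmax <- matrix(0, nt, nt)
    for (k in 0:(mm - 1L)) {
      v <- x[(1:nt) + k]
      dk <- abs(outer(v, v, "-"))
      dmax <- pmax(dmax, dk)
    }
    cnt <- rowSums(dmax <= r)   # self-match included
    mean(log(cnt / nt))
  }
  max(0, phi(m) - phi(m + 1L))
}

#' Extract the full 15-feature HRV vector for one epoch
#'
#' Runs all HRV feature families on the cleaned RR series of a
#' `beat_series` (after [remove_artifacts()]). Individual feature failures
#' yield NA in that slot; fewer than `min_beats` cleaned intervals flags the
#' whole vector missing.
#'
#' @param beats A `beat_series` with `cleaned_rr`, or a bare numeric RR
#'   vector (ms) already cleaned.
#' @param min_beats Minimum cleaned RR intervals for a usable epoch
#'   (default 10).
#' @return Named numeric vector of length 15 in the order of
#'   [hrv_feature_names()]; attribute `missing = TRUE` when the epoch is
#'   unusable.
#' @export
extract_hrv <- function(beats, min_beats = 10) {
  rr <- if (inherits(beats, "beat_series")) {
    if (is.null(beats$cleaned_rr)) beats <- remove_artifacts(beats)
    beats$cleaned_rr
  } else as.numeric(beats)
  out <- setNames(rep(NA_real_, 15), hrv_feature_names())
  if (length(rr) < min_beats) {
    attr(out, "missing") <- TRUE
    return(out)
  }
  td <- hrv_time_domain(rr)
  rm <- hrv_return_map(relative_rr(rr))
  ge <- hrv_geometric(rr)
  pc <- hrv_poincare(rr)
  sp <- hrv_spectral(rr)
  out[names(td)] <- td
  out[names(rm)] <- rm
  out[names(ge)] <- ge
  out[names(pc)] <- pc
  out[c("lf", "hf", "lf_hf")] <- sp[c("lf", "hf", "lf_hf")]
  out["apen"] <- approximate_entropy(rr)
  out
}
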