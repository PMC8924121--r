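# Skin-conductance preprocessing and tonic decomposition ----------------------

# Butterworth lowpass as cascaded second-order sections. High orders are
# numerically unusable in single transfer-function form at low normalized
# cutoffs, so the analog prototype poles are paired and bilinear-transformed
# into biquads applied sequentially.
.butter_sos <- function(cutoff_hz, order, fs) {
  wc <- 2 * fs * tan(pi * cutoff_hz / fs)   # prewarped analog cutoff
  k <- seq_len(order)
  poles <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  poles <- poles[Re(poles) < 0]
  # conjugate pairs (and one real pole for odd order)
  upper <- poles[Im(poles) > 1e-9 * wc]
  real_p <- poles[abs(Im(poles)) <= 1e-9 * wc]
  K <- 2 * fs
  sos <- list()
  for (p in upper) {
    a1 <- -2 * Re(p); a0 <- Mod(p)^2
    den0 <- K^2 + a1 * K + a0
    sos[[length(sos) + 1]] <- list(
      b = a0 * c(1, 2, 1) / den0,
      a = c(1, (2 * a0 - 2 * K^2) / den0, (K^2 - a1 * K + a0) / den0))
  }
  for (p in Re(real_p)) {
    den0 <- K - p
    sos[[length(sos) + 1]] <- list(
      b = -p * c(1, 1) / den0,
      a = c(1, (-K - p) / den0))
  }
  sos
}

#' Zero-phase Butterworth lowpass filter
#'
#' Order-`order` Butterworth lowpass (designed as cascaded second-order
#' sections for numerical stability) applied forward and backward
#' ([signal::filtfilt()]) so the net filter has zero phase and DC gain 1.
#'
#' @param rec A `recording`.
#' @param cutoff_hz Cutoff frequency in Hz (default 5).
#' @param order Filter order (default 10).
#' @return The filtered `recording`.
#' @export
lowpass_butterworth <- function(rec, cutoff_hz = 5, order = 10) {
  stopifnot(inherits(rec, "recording"), order >= 1)
  if (cutoff_hz >= rec$fs / 2)
    stop("cutoff must be below the Nyquist frequency")
  x <- rec$samples
  n <- length(x)
  # odd-reflection padding long enough for the filter transient to settle,
  # so edges (and constants) come through undistorted
  pad <- min(n - 1L, ceiling((2 + order) * rec$fs / cutoff_hz))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  for (sec in .butter_sos(cutoff_hz, order, rec$fs)) {
    xp <- signal::filter(sec$b, sec$a, xp)
    xp <- rev(signal::filter(sec$b, sec$a, rev(xp)))
  }
  new_recording(xp[(pad + 1):(pad + n)], rec$fs, rec$channel, rec$t0)
}

# normalized truncated-Gaussian convolution at one sigma (handles edges by
# renormalizing the kernel mass actually inside the signal)
.gauss_smooth_fixed <- function(x, fs, sigma_s, max_window_s) {
  half <- min(floor(3 * sigma_s * fs), floor(max_window_s * fs / 2))
  if (half < 1) return(x)
  kk <- (-half):half
  w <- exp(-0.5 * (kk / (sigma_s * fs))^2)
  n <- length(x)
  num <- stats::filter(c(rep(0, half), x, rep(0, half)), w, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), w, sides = 2)
  as.numeric(num[(half + 1):(half + n)] / den[(half + 1):(half + n)])
}

#' Adaptive Gaussian smoothing
#'
#' Gaussian smoothing whose kernel width adapts to the local slope: wide
#' (up to the cap) over flat tonic stretches, narrow where the signal moves
#' quickly so that SCR onsets are not blurred away. The kernel support never
#' exceeds `max_window_s`. Implemented as a bank of fixed-width Gaussian
#' convolutions blended per sample by the local slope magnitude.
#'
#' @param rec A `recording`.
#' @param max_window_s Maximum kernel support in seconds (default 3).
#' @param n_widths Number of discrete kernel widths in the bank (default 6).
#' @return The smoothed `recording`, with attribute `width_s`: the
#'   per-sample effective kernel support (s), inspectable to verify the cap.
#' @export
adaptive_gaussian_smooth <- function(rec, max_window_s = 3, n_widths = 6) {
  stopifnot(inherits(rec, "recording"), max_window_s > 0)
  x <- rec$samples
  fs <- rec$fs
  n <- length(x)
  sigma_max <- max_window_s / 6          # support = 6 sigma, truncated at cap
  sigmas <- sigma_max / 2^(seq.int(n_widths - 1, 0))
  # local slope magnitude (per second), lightly pre-smoothed
  slope <- abs(c(0, diff(x))) * fs
  slope <- .gauss_smooth_fixed(slope, fs, sigma_max / 2, max_window_s)
  sc <- median(slope[slope > 0])
  if (!is.finite(sc) || sc == 0) sc <- 1
  # map slope to a width index: flat -> widest, steep -> narrowest
  u <- 1 / (1 + (slope / sc)^2)                # in (0, 1]
  idx <- pmin(n_widths, pmax(1L, ceiling(u * n_widths)))
  bank <- vapply(sigmas, function(s) .gauss_smooth_fixed(x, fs, s, max_window_s),
                 numeric(n))
  out <- bank[cbind(seq_len(n), idx)]
  width <- pmin(6 * sigmas[idx], max_window_s)
  res <- new_recording(out, fs, rec$channel, rec$t0)
  attr(res, "width_s") <- width
  res
}

#' Unit-peak Bateman kernel
#'
#' The canonical skin-conductance-response impulse shape
#' `exp(-t/tau2) - exp(-t/tau1)` (zero for `t < 0`), scaled to unit peak.
#' `tau1` is the rise and `tau2` the decay time constant; the kernel
#' degenerates unless `tau1 < tau2`.
#'
#' @param t Times in seconds.
#' @param tau1 Rise time constant (s), default 0.75.
#' @param tau2 Decay time constant (s), default 2.
#' @return Kernel values at `t`.
#' @export
bateman_kernel <- function(t, tau1 = 0.75, tau2 = 2) {
  if (tau1 >= tau2) stop("Bateman kernel requires tau1 < tau2")
  t_peak <- log(tau2 / tau1) * tau1 * tau2 / (tau2 - tau1)
  peak <- exp(-t_peak / tau2) - exp(-t_peak / tau1)
  ifelse(t < 0, 0, (exp(-t / tau2) - exp(-t / tau1)) / peak)
}

# full linear convolution via FFT
.conv_full <- function(x, y) {
  n <- length(x) + length(y) - 1L
  N <- stats::nextn(n, 2)
  Re(fft(fft(c(x, rep(0, N - length(x)))) *
           fft(c(y, rep(0, N - length(y)))), inverse = TRUE))[seq_len(n)] / N
}

# nonnegative ridge-regularized deconvolution by projected FISTA
.nn_deconvolve <- function(y, kernel, lambda = 1e-3, n_iter = 150) {
  n <- length(y)
  klen <- length(kernel)
  conv_k <- function(d) .conv_full(d, kernel)[seq_len(n)]           # K d
  corr_k <- function(r) .conv_full(r, rev(kernel))[klen:(klen + n - 1)]  # K'r
  L <- sum(kernel)^2 + lambda
  d <- numeric(n); z <- d; tk <- 1
  for (it in seq_len(n_iter)) {
    grad <- -corr_k(y - conv_k(z)) + lambda * z
    d_new <- pmax(0, z - grad / L)
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- d_new + ((tk - 1) / tk_new) * (d_new - d)
    d <- d_new; tk <- tk_new
  }
  d
}

# block-mean decimation of a recording to roughly fs_out
.decimate_recording <- function(rec, fs_out) {
  fac <- max(1L, round(rec$fs / fs_out))
  if (fac == 1L) return(rec)
  n <- (length(rec$samples) %/% fac) * fac
  x <- colMeans(matrix(rec$samples[seq_len(n)], nrow = fac))
  new_recording(x, rec$fs / fac, rec$channel, rec$t0)
}

#' Tonic/phasic decomposition of skin conductance
#'
#' Deconvolution-based decomposition in the spirit of continuous
#' decomposition analysis: the (filtered, smoothed) skin-conductance signal
#' is deconvolved against the unit-peak Bateman kernel under a
#' nonnegativity constraint (regularized least squares, not spectral
#' division) to obtain a sudomotor driver; the tonic component is a smooth
#' spline through anchor points placed where the driver is quietest within
#' successive `grid_s` windows; the phasic component is the remainder, and
#' the skin conductance level (SCL) is the mean of the tonic trace.
#'
#' The decomposition runs internally at a reduced rate (`fs_dec`), which is
#' ample for the sub-Hz tonic dynamics.
#'
#' @param rec A filtered + smoothed skin-conductance `recording` (µS).
#' @param tau1_s,tau2_s Bateman time constants (s); defaults 0.75 and 2.
#' @param grid_s Tonic anchor spacing in seconds (default 10).
#' @param fs_dec Internal decomposition rate in Hz (default 10).
#' @return A `tonic_decomposition` list: `tonic`, `phasic`, `driver`
#'   (traces at `fs` = the internal rate), `t` (times, s), `scl` (µS; NA
#'   and flagged when outside the 0.2--100 µS measuring range), and flags
#'   `low_confidence`, `scl_missing`.
#' @export
decompose_tonic <- function(rec, tau1_s = 0.75, tau2_s = 2, grid_s = 10,
                            fs_dec = 10) {
  stopifnot(inherits(rec, "recording"))
  if (tau1_s >= tau2_s) stop("Bateman kernel requires tau1 < tau2")
  dur <- length(rec$samples) / rec$fs
  if (dur < grid_s) stop("signal shorter than the tonic grid spacing")
  dec <- .decimate_recording(rec, fs_dec)
  y <- dec$samples
  fs <- dec$fs
  n <- length(y)
  tt <- dec$t0 + (seq_len(n) - 1) / fs
  # coarse tonic: running minimum over 2*grid_s, smoothed, so the
  # deconvolution sees (mostly) phasic content
  wmin <- max(3L, round(2 * grid_s * fs))
  half <- wmin %/% 2L
  runmin <- vapply(seq_len(n), function(i)
    min(y[max(1, i - half):min(n, i + half)]), numeric(1))
  coarse <- .gauss_smooth_fixed(runmin, fs, grid_s / 2, 4 * grid_s)
  resid <- pmax(0, y - coarse)
  klen <- ceiling(min(6 * tau2_s, dur / 2) * fs)
  kernel <- bateman_kernel((seq_len(klen) - 1) / fs, tau1_s, tau2_s)
  driver <- .nn_deconvolve(resid, kernel)
  # anchor the tonic where the driver is quietest in each window
  act <- .gauss_smooth_fixed(driver, fs, 1, 8)      # local driver activity
  nwin <- max(2L, floor(dur / grid_s))
  bounds <- round(seq(1, n + 1, length.out = nwin + 1))
  anchor_i <- integer(0)
  low_conf <- FALSE
  phasic_fit <- .conv_full(driver, kernel)[seq_len(n)]
  for (w in seq_len(nwin)) {
    ii <- bounds[w]:(bounds[w + 1] - 1)
    anchor_i <- c(anchor_i, ii[which.min(act[ii])])
  }
  thr <- quantile(act, 0.75, names = FALSE)
  if (all(act[anchor_i] > thr) && thr > 0) {
    # no quiescent stretch anywhere: fall back to the smoothed running min
    low_conf <- TRUE
    tonic <- coarse
  } else {
    av <- y[anchor_i] - phasic_fit[anchor_i]
    tonic <- spline(tt[anchor_i], av, xout = tt, method = "natural")$y
  }
  tonic <- pmin(tonic, y)               # phasic nonnegativity up to noise
  phasic <- y - tonic
  scl <- mean(tonic)
  scl_missing <- !is.finite(scl) || scl < 0.2 || scl > 100
  structure(list(tonic = tonic, phasic = phasic, driver = driver, t = tt,
                 fs = fs, scl = if (scl_missing) NA_real_ else scl,
                 low_confidence = low_conf, scl_missing = scl_missing),
            class = "tonic_decomposition")
}
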