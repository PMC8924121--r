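# Synthetic cohort generator --------------------------------------------------
# Seeded generator for the study design the pipeline analyses: per
# participant, four 5-min resting epochs with ECG and skin-conductance
# recordings, dimensional emotion ratings (valence/arousal/dominance) and a
# STAI-S score per epoch, all driven by a latent anxiety level in [0, 1].
# Ground truth (latent state, R-peak times, tonic means) is retained so that
# every downstream stage can be validated by round-trip.

#' Effect configuration for the synthetic cohort
#'
#' Slopes, intercepts, noise SDs, RR modulation and skin-conductance
#' parameters that couple the latent anxiety level to the observables. The
#' default slope signs encode the expected psychophysiology: arousal, skin
#' conductance level, heart rate and RMSSD rise with anxiety; valence and
#' dominance fall.
#'
#' @param stai_slope,stai_intercept,stai_sd STAI-S (raw 20--80 scale).
#' @param valence_slope,arousal_slope,dominance_slope,vad_intercepts,vad_sd
#'   Emotion ratings (1--9).
#' @param mean_rr_slope_ms,mean_rr_intercept_ms,rr_noise_sd_ms Mean RR (ms);
#'   the negative slope makes heart rate increase with anxiety.
#' @param lf_amp_ms,lf_hz LF RR modulation amplitude (ms) and frequency (Hz).
#' @param hf_amp_base_ms,hf_amp_slope_ms,hf_hz HF RR modulation; the positive
#'   slope makes RMSSD rise with anxiety.
#' @param scl_slope_us,scl_intercept_us Tonic skin conductance level (µS).
#' @param scr_rate_per_min,scr_amp_mean_us Phasic response rate and mean
#'   amplitude.
#' @param tau1_s,tau2_s Bateman rise/decay time constants (s).
#' @param ecg_noise_sd_mv,sc_noise_sd_us Additive recording noise.
#' @param anxiety_step_sd Step SD of the latent anxiety random walk.
#' @return A validated list of class `effect_config`.
#' @export
effect_config <- function(stai_slope = 30, stai_intercept = 32, stai_sd = 4,
                          valence_slope = -3, arousal_slope = 4,
                          dominance_slope = -3,
                          vad_intercepts = c(valence = 6.5, arousal = 2.5,
                                             dominance = 6.5),
                          vad_sd = 0.4,
                          mean_rr_slope_ms = -250, mean_rr_intercept_ms = 950,
                          rr_noise_sd_ms = 8,
                          lf_amp_ms = 25, lf_hz = 0.1,
                          hf_amp_base_ms = 15, hf_amp_slope_ms = 25,
                          hf_hz = 0.25,
                          scl_slope_us = 3, scl_intercept_us = 4,
                          scr_rate_per_min = 8, scr_amp_mean_us = 0.4,
                          tau1_s = 0.75, tau2_s = 2,
                          ecg_noise_sd_mv = 0.05, sc_noise_sd_us = 0.02,
                          anxiety_step_sd = 0.25) {
  cfg <- as.list(environment())
  sds <- c(stai_sd, vad_sd, rr_noise_sd_ms, ecg_noise_sd_mv, sc_noise_sd_us,
           anxiety_step_sd)
  if (any(sds < 0)) stop("noise SDs must be nonnegative")
  if (lf_hz <= 0 || lf_hz >= 0.5 || hf_hz <= 0 || hf_hz >= 0.5)
    stop("modulation frequencies must lie inside (0, 0.5) Hz")
  if (tau1_s >= tau2_s) stop("Bateman kernel requires tau1 < tau2")
  structure(cfg, class = "effect_config")
}

#' Simulate an RR-interval series with oscillatory modulation
#'
#' Generates beat-to-beat RR intervals
#' `RR_i = mean + lf_amp sin(2 pi lf_hz t_i) + hf_amp sin(2 pi hf_hz t_i) +
#' noise` where `t_i` is the cumulative beat time, until the beats span
#' `duration_s`.
#'
#' @param mean_rr_ms Mean RR in ms; must lie in the 50--220 bpm band.
#' @param lf_amp_ms,hf_amp_ms Modulation amplitudes (ms).
#' @param lf_hz,hf_hz Modulation frequencies (Hz).
#' @param duration_s Target span in seconds.
#' @param noise_sd_ms Gaussian beat-to-beat noise SD (ms), default 0.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return Numeric vector of RR intervals (ms).
#' @export
simulate_rr_series <- function(mean_rr_ms, lf_amp_ms = 0, hf_amp_ms = 0,
                               lf_hz = 0.1, hf_hz = 0.25, duration_s = 60,
                               noise_sd_ms = 0, seed = NULL) {
  if (mean_rr_ms < .RR_MIN_MS || mean_rr_ms > .RR_MAX_MS)
    stop(sprintf("mean_rr_ms must lie in [%.1f, %.1f] ms (50-220 bpm)",
                 .RR_MIN_MS, .RR_MAX_MS))
  stopifnot(duration_s > 0)
  if (!is.null(seed)) set.seed(seed)
  # generous preallocation, trimmed to span
  n_max <- ceiling(duration_s * 1000 / .RR_MIN_MS) + 2L
  rr <- numeric(n_max)
  t <- 0
  i <- 0L
  while (t < duration_s) {
    i <- i + 1L
    r <- mean_rr_ms +
      lf_amp_ms * sin(2 * pi * lf_hz * t) +
      hf_amp_ms * sin(2 * pi * hf_hz * t) +
      (if (noise_sd_ms > 0) rnorm(1, 0, noise_sd_ms) else 0)
    r <- max(r, .RR_MIN_MS)
    rr[i] <- r
    t <- t + r / 1000
  }
  rr[seq_len(i)]
}

# QRS-like template: Mexican-hat spike, ~80 ms support, unit peak
.qrs_template <- function(fs, sigma_s = 0.012, half_width_s = 0.04) {
  tau <- seq(-half_width_s, half_width_s, by = 1 / fs)
  (1 - (tau / sigma_s)^2) * exp(-tau^2 / (2 * sigma_s^2))
}

#' Synthesize an ECG recording from an RR series
#'
#' Places a QRS-like Mexican-hat spike (unit peak, about 80 ms wide) at each
#' cumulative beat time, adds sinusoidal baseline wander and Gaussian noise.
#' Ground-truth R times are snapped to the sample grid and returned exactly.
#'
#' @param rr_ms RR intervals in ms.
#' @param fs Sampling frequency in Hz (the acquisition standard is 1000).
#' @param duration_s Total recording length (s); defaults to just past the
#'   last beat.
#' @param start_s Time of the first beat (s), default 0.5.
#' @param noise_sd Additive noise SD in mV (default 0.05).
#' @param wander_amp,wander_hz Baseline wander amplitude (mV) and frequency.
#' @param seed Optional seed.
#' @return List with `recording` (class `recording`, channel `"ecg"`) and
#'   `r_times` (s).
#' @export
synthesize_ecg <- function(rr_ms, fs = 1000, duration_s = NULL, start_s = 0.5,
                           noise_sd = 0.05, wander_amp = 0.1, wander_hz = 0.25,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  beat_t <- start_s + c(0, cumsum(rr_ms)) / 1000
  if (is.null(duration_s)) duration_s <- max(beat_t) + 0.5
  n <- round(duration_s * fs)
  beat_t <- beat_t[beat_t < duration_s - 0.05]
  idx <- round(beat_t * fs) + 1L
  r_times <- (idx - 1L) / fs
  x <- numeric(n)
  tpl <- .qrs_template(fs)
  hw <- (length(tpl) - 1L) %/% 2L
  for (i in idx) {
    lo <- max(1L, i - hw); hi <- min(n, i + hw)
    x[lo:hi] <- x[lo:hi] + tpl[(lo - i + hw + 1L):(hi - i + hw + 1L)]
  }
  tt <- (seq_len(n) - 1) / fs
  x <- x + wander_amp * sin(2 * pi * wander_hz * tt)
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  list(recording = new_recording(x, fs, "ecg"), r_times = r_times)
}

#' Synthesize a skin-conductance recording
#'
#' `SC(t) = tonic(t) + sum_k amp_k bateman(t - t_k) + noise`, with the
#' unit-peak Bateman kernel of [bateman_kernel()].
#'
#' @param tonic_fn Function of time (s) returning the tonic level (µS);
#'   values must stay within the 0.2--100 µS measuring range.
#' @param scr_times Onset times (s) of phasic responses.
#' @param scr_amps Amplitudes (µS), recycled against `scr_times`.
#' @param tau1_s,tau2_s Bateman time constants (s).
#' @param fs Sampling frequency (Hz).
#' @param duration_s Recording length (s).
#' @param noise_sd Additive noise SD (µS), default 0.
#' @param seed Optional seed.
#' @return List with `recording` (channel `"gsr"`) and `tonic` (the
#'   ground-truth tonic trace, µS).
#' @export
synthesize_gsr <- function(tonic_fn, scr_times = numeric(0),
                           scr_amps = numeric(0), tau1_s = 0.75, tau2_s = 2,
                           fs = 1000, duration_s = 60, noise_sd = 0,
                           seed = NULL) {
  if (tau1_s >= tau2_s) stop("Bateman kernel requires tau1 < tau2")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  tonic <- tonic_fn(tt)
  if (length(tonic) == 1) tonic <- rep(tonic, n)
  if (any(tonic < 0.2 | tonic > 100))
    stop("tonic values must lie within the 0.2-100 uS measuring range")
  x <- tonic
  if (length(scr_times)) {
    amps <- rep_len(scr_amps, length(scr_times))
    for (k in seq_along(scr_times)) {
      i0 <- floor(scr_times[k] * fs) + 1L
      if (i0 > n) next
      seg <- i0:n
      x[seg] <- x[seg] + amps[k] *
        bateman_kernel(tt[seg] - scr_times[k], tau1_s, tau2_s)
    }
  }
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  list(recording = new_recording(x, fs, "gsr"), tonic = tonic)
}

# latent anxiety: per-participant random walk clipped to [0, 1]
.anxiety_walk <- function(n_epochs, step_sd) {
  a <- numeric(n_epochs)
  a[1] <- runif(1, 0.2, 0.8)
  for (e in seq_len(n_epochs)[-1])
    a[e] <- min(1, max(0, a[e - 1] + rnorm(1, 0, step_sd)))
  a
}

# per-epoch observable parameters from a latent anxiety value
.epoch_params <- function(a, fx) {
  list(
    stai = min(80, max(20, fx$stai_intercept + fx$stai_slope * a +
                         rnorm(1, 0, fx$stai_sd))),
    valence = min(9, max(1, fx$vad_intercepts[["valence"]] +
                           fx$valence_slope * a + rnorm(1, 0, fx$vad_sd))),
    arousal = min(9, max(1, fx$vad_intercepts[["arousal"]] +
                           fx$arousal_slope * a + rnorm(1, 0, fx$vad_sd))),
    dominance = min(9, max(1, fx$vad_intercepts[["dominance"]] +
                             fx$dominance_slope * a + rnorm(1, 0, fx$vad_sd))),
    mean_rr = min(1150, max(350, fx$mean_rr_intercept_ms +
                              fx$mean_rr_slope_ms * a)),
    hf_amp = max(0, fx$hf_amp_base_ms + fx$hf_amp_slope_ms * a),
    scl = fx$scl_intercept_us + fx$scl_slope_us * a
  )
}

#' Simulate a full synthetic resting-state cohort
#'
#' Generates, for each participant, a latent anxiety random walk over
#' `epochs_per_participant` resting epochs and the resulting observables:
#' continuous ECG and skin-conductance recordings (optional), an epoch
#' schedule, VAD ratings, raw STAI-S scores, and ground-truth sidecars
#' (latent state, exact R-peak times, true tonic means).
#'
#' @param n_participants Number of participants (default 25, >= 2).
#' @param epochs_per_participant Resting epochs per participant (default 4;
#'   the first is the baseline).
#' @param effects An [effect_config()].
#' @param seed Integer seed (all randomness is derived from it).
#' @param epoch_s Epoch duration in seconds (default 300, i.e. 5 min).
#' @param fs Sampling frequency (Hz), default 1000.
#' @param signals If `FALSE`, skip waveform synthesis and return only
#'   labels, schedule and ground truth (fast; for label-level studies).
#' @return A list of class `synthetic_cohort` with elements `schedule`,
#'   `labels`, `latent`, `truth`, `recordings` (named by participant, each
#'   `list(ecg, gsr, r_times)`), plus the generating `effects`, `seed`,
#'   `fs`, `epoch_s`.
#' @export
simulate_cohort <- function(n_participants = 25, epochs_per_participant = 4,
                            effects = effect_config(), seed = 1,
                            epoch_s = 300, fs = 1000, signals = TRUE) {
  if (n_participants < 2) stop("need at least 2 participants")
  if (epochs_per_participant < 2)
    stop("need at least 2 epochs (the first is the baseline)")
  stopifnot(inherits(effects, "effect_config"))
  set.seed(seed)
  ids <- sprintf("P%02d", seq_len(n_participants))
  sched <- lab <- lat <- tru <- vector("list", n_participants)
  recs <- setNames(vector("list", n_participants), ids)
  for (p in seq_len(n_participants)) {
    anx <- .anxiety_walk(epochs_per_participant, effects$anxiety_step_sd)
    ecg_parts <- gsr_parts <- vector("list", epochs_per_participant)
    r_all <- numeric(0)
    rows <- vector("list", epochs_per_participant)
    for (e in seq_len(epochs_per_participant)) {
      par <- .epoch_params(anx[e], effects)
      off <- (e - 1) * epoch_s
      scl_true <- par$scl
      if (signals) {
        rr <- simulate_rr_series(par$mean_rr, effects$lf_amp_ms, par$hf_amp,
                                 effects$lf_hz, effects$hf_hz,
                                 duration_s = epoch_s - 1,
                                 noise_sd_ms = effects$rr_noise_sd_ms)
        ecg <- synthesize_ecg(rr, fs = fs, duration_s = epoch_s,
                              noise_sd = effects$ecg_noise_sd_mv)
        n_scr <- stats::rpois(1, epoch_s / 60 * effects$scr_rate_per_min)
        scr_t <- sort(runif(n_scr, 0, epoch_s - 5))
        scr_a <- rexp(n_scr, 1 / effects$scr_amp_mean_us)
        gsr <- synthesize_gsr(function(t) rep(par$scl, length(t)),
                              scr_t, scr_a, effects$tau1_s, effects$tau2_s,
                              fs = fs, duration_s = epoch_s,
                              noise_sd = effects$sc_noise_sd_us)
        ecg_parts[[e]] <- ecg$recording$samples
        gsr_parts[[e]] <- gsr$recording$samples
        r_all <- c(r_all, ecg$r_times + off)
        scl_true <- mean(gsr$tonic)
      }
      rows[[e]] <- data.frame(
        participant = ids[p], epoch_index = e,
        stai_s = par$stai, valence = par$valence, arousal = par$arousal,
        dominance = par$dominance, anxiety = anx[e],
        mean_rr_true = par$mean_rr, hf_amp_true = par$hf_amp,
        scl_true = scl_true)
    }
    rows <- do.call(rbind, rows)
    sched[[p]] <- data.frame(
      participant = ids[p], condition = "rest",
      epoch_index = seq_len(epochs_per_participant),
      start_s = (seq_len(epochs_per_participant) - 1) * epoch_s,
      end_s = seq_len(epochs_per_participant) * epoch_s)
    lab[[p]] <- rows[c("participant", "epoch_index", "stai_s", "valence",
                       "arousal", "dominance")]
    lat[[p]] <- rows[c("participant", "epoch_index", "anxiety")]
    tru[[p]] <- rows[c("participant", "epoch_index", "anxiety",
                       "mean_rr_true", "hf_amp_true", "scl_true")]
    if (signals) {
      recs[[p]] <- list(
        ecg = new_recording(unlist(ecg_parts), fs, "ecg"),
        gsr = new_recording(unlist(gsr_parts), fs, "gsr"),
        r_times = r_all)
    }
  }
  structure(list(schedule = do.call(rbind, sched),
                 labels = do.call(rbind, lab),
                 latent = do.call(rbind, lat),
                 truth = do.call(rbind, tru),
                 recordings = if (signals) recs else NULL,
                 effects = effects, seed = seed, epoch_s = epoch_s, fs = fs),
            class = "synthetic_cohort")
}

#' Simulate a cohort feature matrix directly at the feature level
#'
#' Emits the raw per-epoch 19-feature observation table that
#' [extract_feature_matrix()] would produce, generated directly from the
#' latent anxiety process without waveform synthesis. Features not driven by
#' the configured effects are generated as physiologically plausible noise
#' around typical resting values. Intended for fast, repeated model-level
#' simulation studies; the waveform route exercises the same statistical
#' structure through the full signal pipeline.
#'
#' @inheritParams simulate_cohort
#' @return A data.frame with columns `participant`, `epoch_index`,
#'   `condition`, the 19 features of [feature_names()], and `stai_s_raw`.
#' @export
simulate_feature_matrix <- function(n_participants = 25,
                                    epochs_per_participant = 4,
                                    effects = effect_config(), seed = 1) {
  cohort <- simulate_cohort(n_participants, epochs_per_participant,
                            effects, seed, signals = FALSE)
  tr <- cohort$truth
  lb <- cohort$labels
  n <- nrow(tr)
  lf_amp <- effects$lf_amp_ms
  rmssd <- pmax(0.5, 1.2 * tr$hf_amp_true + rnorm(n, 0, 3))
  sd_rr <- pmax(1, sqrt((lf_amp^2 + tr$hf_amp_true^2) / 2) + rnorm(n, 0, 3))
  sd1 <- rmssd / sqrt(2) + rnorm(n, 0, 0.5)
  sd2 <- pmax(sd1 + 0.5, sqrt(pmax(0.1, 2 * sd_rr^2 - sd1^2)) + rnorm(n, 0, 2))
  lf <- pmax(1, lf_amp^2 / 2 + rnorm(n, 0, 40))
  hf <- pmax(1, tr$hf_amp_true^2 / 2 + rnorm(n, 0, 40))
  df <- data.frame(
    participant = tr$participant, epoch_index = tr$epoch_index,
    condition = "rest",
    mean_rr = tr$mean_rr_true + rnorm(n, 0, 5),
    sd_rr = sd_rr,
    rm_median = pmax(0.001, 0.03 + rnorm(n, 0, 0.005)),
    rm_iqr = pmax(0.001, 0.015 + rnorm(n, 0, 0.003)),
    rmssd = rmssd,
    pnn50 = pmin(1, pmax(0, 0.1 + 0.01 * (rmssd - 30) + rnorm(n, 0, 0.03))),
    tri = pmax(1, 4 + sd_rr / 10 + rnorm(n, 0, 0.5)),
    tinn = pmax(10, 5 * sd_rr + rnorm(n, 0, 15)),
    sd1 = sd1, sd2 = sd2, sd1_sd2 = sd1 / sd2,
    lf = lf, hf = hf, lf_hf = lf / hf,
    apen = pmax(0.05, 1 + rnorm(n, 0, 0.15)),
    scl = tr$scl_true + rnorm(n, 0, 0.1),
    valence = lb$valence, arousal = lb$arousal, dominance = lb$dominance,
    stai_s_raw = lb$stai_s)
  df
}
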