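# Independent brute-force oracles used across the suite ----------------------

# sort-and-trim per window, truncated at the edges
oracle_trimmed_mean <- function(x, half_left, half_right, trim_frac) {
  sapply(seq_along(x), function(i) {
    w <- x[max(1, i - half_left):min(length(x), i + half_right)]
    k <- floor(trim_frac * length(w))
    if (2 * k >= length(w)) k <- (length(w) - 1) %/% 2
    s <- sort(w)
    mean(s[(k + 1):(length(s) - k)])
  })
}

# direct template-counting ApEn (Pincus), self-matches included
oracle_apen <- function(x, m = 2, r_frac = 0.2) {
  n <- length(x)
  r <- r_frac * sd(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    cnt <- numeric(nt)
    for (i in 1:nt) {
      for (j in 1:nt) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r)
          cnt[i] <- cnt[i] + 1
      }
    }
    mean(log(cnt / nt))
  }
  phi(m) - phi(m + 1)
}

# Benjamini-Hochberg step-up, written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (k in m:1) {
    running <- min(running, p[o[k]] * m / k)
    adj[o[k]] <- min(1, running)
  }
  adj
}

# short synthetic ECG with known R times
make_ecg_fixture <- function(seed, duration_s = 60, noise_sd = 0.05) {
  set.seed(seed)
  rr <- simulate_rr_series(sample(seq(600, 1000, 50), 1),
                           lf_amp_ms = 25, hf_amp_ms = 25,
                           duration_s = duration_s, noise_sd_ms = 8)
  synthesize_ecg(rr, noise_sd = noise_sd)
}

# skin conductance with ramping tonic and Poisson phasic responses
make_gsr_fixture <- function(seed, duration_s = 300, fs = 100,
                             scr_per_min = 8) {
  set.seed(seed)
  n_scr <- rpois(1, duration_s / 60 * scr_per_min)
  scr_t <- sort(runif(n_scr, 0, duration_s - 5))
  scr_a <- rexp(max(n_scr, 1), 1 / 0.4)[seq_len(n_scr)]
  synthesize_gsr(function(t) 4 + 2 * t / duration_s, scr_t, scr_a,
                 fs = fs, duration_s = duration_s, noise_sd = 0.02)
}

# EDA preprocessing chain as run by the pipeline
preprocess_gsr <- function(rec) {
  adaptive_gaussian_smooth(lowpass_butterworth(rec, 5, 10), 3)
}
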