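# small full-signal cohort shared by the assembly tests
local_cohort <- local({
  co <- NULL
  function() {
    if (is.null(co))
      co <<- simulate_cohort(n_participants = 3, epochs_per_participant = 4,
                             seed = 21, epoch_s = 60)
    co
  }
})

test_that("epoch slices honour the half-open schedule", {
  co <- local_cohort()
  slices <- segment_epochs(co$recordings, co$schedule)
  expect_length(slices, 12)
  durs <- sapply(slices, function(s) length(s$ecg$samples) / s$ecg$fs)
  expect_true(all(durs == 60))
  # adjacent epochs share no sample
  s1 <- slices[[1]]; s2 <- slices[[2]]
  n_total <- length(co$recordings$P01$ecg$samples)
  expect_equal(length(s1$ecg$samples) + length(s2$ecg$samples),
               length(co$recordings$P01$ecg$samples[1:(2 * 60 * 1000)]))
  bad <- co$schedule
  bad$end_s[1] <- 1e6
  expect_error(segment_epochs(co$recordings, bad), "outside the recording")
})

test_that("a 65-picture run at 5 pictures per epoch gives 13 epochs", {
  # task-epoch arithmetic on the schedule representation
  n_pictures <- 65
  per_epoch <- 5
  sched <- data.frame(participant = "P01", condition = "neutral_iaps",
                      epoch_index = seq_len(n_pictures / per_epoch),
                      start_s = (seq_len(13) - 1) * 60,
                      end_s = seq_len(13) * 60)
  expect_equal(nrow(sched), 13)
  expect_true(all(sched$end_s - sched$start_s == 60))
})

test_that("the observation table has 19 features and channel independence", {
  co <- local_cohort()
  slices <- segment_epochs(co$recordings, co$schedule)
  raw <- extract_feature_matrix(slices, co$labels)
  expect_equal(nrow(raw), 12)
  expect_length(feature_names(), 19)
  expect_true(all(feature_names() %in% names(raw)))
  expect_equal(attr(raw, "missing_fraction"), 0)
  # kill the ECG of one epoch: HRV missing, SCL intact
  broken <- slices
  broken[[2]]$ecg <- new_recording(rep(0.01, 60 * 1000), 1000, "ecg",
                                   t0 = broken[[2]]$ecg$t0)
  raw2 <- suppressWarnings(extract_feature_matrix(broken, co$labels))
  expect_true(all(is.na(raw2[2, hrv_feature_names()])))
  expect_false(is.na(raw2$scl[2]))
  expect_false(anyNA(raw2[-2, hrv_feature_names()]))
})

test_that("baseline normalization subtracts epoch 1 and drops it", {
  raw <- simulate_feature_matrix(25, 4, seed = 2)
  norm <- baseline_normalize(raw)
  expect_equal(nrow(norm), 75)                      # 25 x 3 analysis rows
  expect_false(1 %in% norm$epoch_index)
  p1 <- raw[raw$participant == "P01", ]
  expect_equal(norm$mean_rr[norm$participant == "P01"],
               p1$mean_rr[-1] - p1$mean_rr[1], tolerance = 1e-12)
  expect_equal(norm$stai_s_norm[norm$participant == "P01"],
               p1$stai_s_raw[-1] - p1$stai_s_raw[1], tolerance = 1e-12)
  # an epoch identical to baseline becomes an all-zero feature row
  raw2 <- raw[raw$participant == "P01", ][c(1, 1, 2), ]
  raw2$epoch_index <- 1:3
  norm2 <- baseline_normalize(raw2)
  expect_equal(unname(as.numeric(norm2[1, feature_names()])), rep(0, 19))
})

test_that("within-participant z-scoring centres every participant", {
  raw <- simulate_feature_matrix(10, 4, seed = 3)
  z <- zscore_within_participant(baseline_normalize(raw))
  for (pid in unique(z$participant)) {
    sub <- as.matrix(z[z$participant == pid, feature_names()])
    expect_equal(max(abs(colMeans(sub))), 0, tolerance = 1e-9)
    expect_equal(unname(apply(sub, 2, sd)), rep(1, 19), tolerance = 1e-9)
  }
  expect_equal(max(abs(tapply(z$stai_s_norm, z$participant, mean))), 0,
               tolerance = 1e-9)
  # zero-variance feature -> zeros, not NaN
  raw$scl <- 1
  z2 <- zscore_within_participant(baseline_normalize(raw))
  expect_true(all(z2$scl == 0))
  expect_true("scl" %in% attr(z2, "degenerate_columns"))
  # single-row participants are rejected
  expect_error(zscore_within_participant(
    baseline_normalize(raw[raw$epoch_index <= 2, ])), "single analysis row")
})

test_that("TSR imputation recovers an exact rank-3 matrix", {
  set.seed(4)
  X <- matrix(rnorm(75 * 3), 75, 3) %*% matrix(rnorm(3 * 19), 3, 19)
  mask <- matrix(runif(75 * 19) < 0.02, 75, 19)
  M <- X; M[mask] <- NA
  out <- impute_tsr(M)
  expect_lt(max(abs(out[mask] - X[mask])), 1e-6)
  expect_identical(out[!mask], X[!mask])            # observed untouched
  expect_true(attr(out, "converged"))
})

test_that("imputation is exact identity without missing cells and monotone
           under nested masks", {
  set.seed(5)
  X <- matrix(rnorm(75 * 3), 75, 3) %*% matrix(rnorm(3 * 19), 3, 19)
  expect_identical(unclass(impute_tsr(X))[seq_along(X)], X[seq_along(X)])
  big <- sample(length(X), 30)
  core <- big[1:10]                      # cells shared by every mask
  errs <- sapply(c(10, 20, 30), function(k) {
    m <- X
    m[big[seq_len(k)]] <- NA
    max(abs(impute_tsr(m)[core] - X[core]))
  })
  expect_true(all(diff(errs) >= -1e-7))
  expect_error(impute_tsr({m <- X; m[runif(length(m)) < 0.6] <- NA; m}),
               "half")
  expect_error(impute_tsr(X[1:4, 1:4], n_components = 4), "below")
})

test_that("the assembled matrix keeps row identity and has no NA", {
  raw <- simulate_feature_matrix(25, 4, seed = 6)
  # knock out ~2% of feature cells as extraction failures
  set.seed(6)
  fm <- as.matrix(raw[feature_names()])
  fm[matrix(runif(length(fm)) < 0.02, nrow(fm))] <- NA
  raw[feature_names()] <- fm
  mat <- assemble_cohort_matrix(raw)
  expect_equal(dim(as.matrix(mat[feature_names()])), c(75, 19))
  expect_false(anyNA(mat[feature_names()]))
  expect_equal(sort(unique(mat$participant)), sort(unique(raw$participant)))
  expect_true(all(table(mat$participant) == 3))
  expect_true(attr(mat, "imputation")$converged)
})
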