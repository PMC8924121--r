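# Epoching, feature-matrix assembly, normalization, imputation ---------------

#' Slice recordings into epochs
#'
#' Cuts each participant's channels into half-open `[start_s, end_s)`
#' slices according to the epoch schedule.
#'
#' @param recordings Named list (by participant) of
#'   `list(ecg = recording, gsr = recording)`.
#' @param schedule Data frame with columns `participant`, `condition`,
#'   `epoch_index`, `start_s`, `end_s`.
#' @return List of epoch slices, each
#'   `list(participant, condition, epoch_index, ecg, gsr)`.
#' @export
segment_epochs <- function(recordings, schedule) {
  stopifnot(all(c("participant", "epoch_index", "start_s", "end_s") %in%
                  names(schedule)))
  if (any(schedule$end_s <= schedule$start_s))
    stop("epoch end must exceed epoch start")
  slice <- function(rec, s, e, id) {
    n <- length(rec$samples)
    i0 <- round((s - rec$t0) * rec$fs) + 1L
    i1 <- round((e - rec$t0) * rec$fs)        # half-open: excludes t = end
    if (i0 < 1L || i1 > n)
      stop(sprintf("epoch %s lies outside the recording", id))
    new_recording(rec$samples[i0:i1], rec$fs, rec$channel, t0 = s)
  }
  out <- vector("list", nrow(schedule))
  for (k in seq_len(nrow(schedule))) {
    row <- schedule[k, ]
    chans <- recordings[[row$participant]]
    if (is.null(chans)) stop(sprintf("no recordings for %s", row$participant))
    id <- sprintf("%s/epoch %d", row$participant, row$epoch_index)
    out[[k]] <- list(
      participant = row$participant,
      condition = if ("condition" %in% names(row)) row$condition else NA,
      epoch_index = row$epoch_index,
      ecg = slice(chans$ecg, row$start_s, row$end_s, id),
      gsr = slice(chans$gsr, row$start_s, row$end_s, id))
  }
  out
}

#' ECG beat detection signal
#'
#' The robust baseline estimated by the trimmed moving average is
#' subtracted from the raw ECG (removing wander and movement artifacts
#' while leaving the sharp QRS complexes intact) and the residual is
#' z-scored for beat annotation.
#'
#' @param rec Raw ECG `recording`.
#' @param window_s,trim_frac Passed to [trimmed_moving_average()].
#' @return A z-scored `recording` ready for [detect_beats()].
#' @export
preprocess_ecg <- function(rec, window_s = 0.2, trim_frac = 0.25) {
  base <- trimmed_moving_average(rec, window_s, trim_frac)
  zscore_signal(new_recording(rec$samples - base$samples, rec$fs,
                              rec$channel, rec$t0))
}

# single-epoch ECG -> cleaned beat series (NULL-safe)
.epoch_beats <- function(ecg, params) {
  det <- tryCatch(preprocess_ecg(ecg, params$window_s, params$trim_frac),
                  error = function(e) NULL)
  if (is.null(det)) return(NULL)
  r <- suppressWarnings(detect_beats(det, params$threshold_frac))
  if (length(r) < 2) return(NULL)
  remove_artifacts(compute_rr(r), params$rrr_threshold)
}

# single-epoch GSR -> scl scalar (NA when out of range / failed)
.epoch_scl <- function(gsr, params) {
  out <- tryCatch({
    f <- lowpass_butterworth(gsr, params$butter_cutoff_hz, params$butter_order)
    f <- .decimate_recording(f, params$eda_fs_work)
    s <- adaptive_gaussian_smooth(f, params$smooth_max_window_s)
    decompose_tonic(s, params$tau1_s, params$tau2_s, params$grid_s,
                    params$eda_fs_dec)$scl
  }, error = function(e) NA_real_)
  out
}

#' Default analysis parameters
#'
#' All tunable constants of the extraction pipeline in one list: trimmed
#' moving average window 0.2 s with 25% trim; 50--220 bpm validity band
#' (built into the RR stage); relative-RR artifact cutoff 0.2; Butterworth
#' lowpass 5 Hz / order 10; adaptive smoothing window cap 3 s; Bateman
#' constants 0.75 / 2 s; LF band 0.04--0.15 Hz and HF band 0.15--0.40 Hz
#' with 1/128 s histogram bins (inside the HRV features); TSR imputation
#' with 3 components, 5000 iterations, tolerance 1e-9.
#'
#' @param ... Overrides for individual entries.
#' @return A named list.
#' @export
analysis_params <- function(...) {
  p <- list(window_s = 0.2, trim_frac = 0.25, threshold_frac = 0.5,
            rrr_threshold = 0.2, min_beats = 10,
            butter_cutoff_hz = 5, butter_order = 10,
            smooth_max_window_s = 3, tau1_s = 0.75, tau2_s = 2, grid_s = 10,
            eda_fs_work = 20, eda_fs_dec = 10,
            tsr_ncomp = 3, tsr_max_iter = 5000, tsr_tol = 1e-9,
            baseline_method = "subtract")
  over <- list(...)
  p[names(over)] <- over
  p
}

#' Extract the raw 19-feature observation matrix
#'
#' Runs the ECG and EDA pipelines on every epoch slice and joins the VAD
#' ratings and STAI-S labels. Channel failures become missingness, never
#' errors: an epoch with too few cleaned beats has its 15 HRV features
#' missing while SCL survives, and vice versa.
#'
#' @param slices Epoch slices from [segment_epochs()].
#' @param labels Data frame with `participant`, `epoch_index`, `stai_s`,
#'   `valence`, `arousal`, `dominance`.
#' @param params An [analysis_params()] list.
#' @return A data.frame: `participant`, `epoch_index`, `condition`, the 19
#'   features of [feature_names()], `stai_s_raw`.
#' @export
extract_feature_matrix <- function(slices, labels, params = analysis_params()) {
  rows <- vector("list", length(slices))
  for (k in seq_along(slices)) {
    sl <- slices[[k]]
    beats <- .epoch_beats(sl$ecg, params)
    hrv <- if (is.null(beats)) {
      setNames(rep(NA_real_, 15), hrv_feature_names())
    } else extract_hrv(beats, params$min_beats)
    scl <- .epoch_scl(sl$gsr, params)
    lab <- labels[labels$participant == sl$participant &
                    labels$epoch_index == sl$epoch_index, , drop = FALSE]
    if (nrow(lab) != 1)
      stop(sprintf("no unique label row for %s/epoch %d",
                   sl$participant, sl$epoch_index))
    row <- data.frame(participant = sl$participant,
                      epoch_index = sl$epoch_index,
                      condition = sl$condition)
    row[hrv_feature_names()] <- as.list(unname(hrv[hrv_feature_names()]))
    row$scl <- scl
    row$valence <- lab$valence
    row$arousal <- lab$arousal
    row$dominance <- lab$dominance
    row$stai_s_raw <- lab$stai_s
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "missing_fraction") <-
    mean(is.na(as.matrix(out[feature_names()])))
  out
}

#' Normalize observations to each participant's baseline epoch
#'
#' The first epoch of each participant is the baseline; it is subtracted
#' from that participant's remaining epochs (features and the STAI-S label
#' alike) and dropped from the analysis set. `method = "ratio"` divides
#' instead, for sensitivity analyses.
#'
#' @param mat Output of [extract_feature_matrix()] (or
#'   [simulate_feature_matrix()]).
#' @param method `"subtract"` (default) or `"ratio"`.
#' @return The analysis rows with baseline-normalized features and a
#'   `stai_s_norm` column (raw scores retained in `stai_s_raw`).
#' @export
baseline_normalize <- function(mat, method = c("subtract", "ratio")) {
  method <- match.arg(method)
  feats <- feature_names()
  out <- NULL
  for (pid in unique(mat$participant)) {
    rows <- mat[mat$participant == pid, , drop = FALSE]
    rows <- rows[order(rows$epoch_index), , drop = FALSE]
    if (nrow(rows) < 2) {
      warning(sprintf("participant %s has no post-baseline epochs; excluded",
                      pid))
      next
    }
    base <- rows[1, , drop = FALSE]
    rest <- rows[-1, , drop = FALSE]
    if (method == "subtract") {
      rest[feats] <- sweep(as.matrix(rest[feats]), 2,
                           as.numeric(base[1, feats]), "-")
      rest$stai_s_norm <- rest$stai_s_raw - base$stai_s_raw
    } else {
      rest[feats] <- sweep(as.matrix(rest[feats]), 2,
                           as.numeric(base[1, feats]), "/")
      rest$stai_s_norm <- rest$stai_s_raw / base$stai_s_raw
    }
    out <- rbind(out, rest)
  }
  rownames(out) <- NULL
  out
}

#' Z-score features (and the label) within each participant
#'
#' Per participant and per feature, centre to mean 0 and scale by the
#' sample SD over that participant's analysis rows. Zero-variance features
#' become all zeros (flagged via attribute `degenerate_columns`).
#'
#' @param mat Output of [baseline_normalize()].
#' @return The matrix with features and `stai_s_norm` z-scored within
#'   participant.
#' @export
zscore_within_participant <- function(mat) {
  cols <- c(feature_names(), "stai_s_norm")
  degenerate <- character(0)
  for (pid in unique(mat$participant)) {
    sel <- mat$participant == pid
    if (sum(sel) < 2)
      stop(sprintf("participant %s has a single analysis row", pid))
    for (cl in cols) {
      v <- mat[sel, cl]
      s <- sd(v, na.rm = TRUE)
      m <- mean(v, na.rm = TRUE)
      if (!is.finite(s) || s == 0) {
        mat[sel, cl] <- ifelse(is.na(v), NA_real_, 0)
        degenerate <- union(degenerate, cl)
      } else {
        mat[sel, cl] <- (v - m) / s
      }
    }
  }
  attr(mat, "degenerate_columns") <- degenerate
  mat
}

#' Trimmed-scores-regression imputation of missing cells
#'
#' Iterative PCA imputation: missing cells start at the column means; each
#' iteration fits an `n_components` principal subspace to the completed
#' matrix and re-predicts the missing cells of every incomplete row from
#' the scores regressed on its observed part, until the largest cell change
#' drops below `tol` or `max_iter` is reached. Observed cells are never
#' altered.
#'
#' @param x Numeric matrix with `NA` marking missing cells.
#' @param n_components Number of principal components (default 3).
#' @param max_iter Maximum iterations (default 5000).
#' @param tol Convergence tolerance on the largest cell change
#'   (default 1e-9).
#' @return The completed matrix, with attributes `converged`, `iterations`,
#'   `missing_fraction`.
#' @export
impute_tsr <- function(x, n_components = 3, max_iter = 5000, tol = 1e-9) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (n_components >= min(dim(x)))
    stop("n_components must be below min(nrow, ncol)")
  miss <- is.na(x)
  frac <- mean(miss)
  if (frac == 0) {
    attr(x, "converged") <- TRUE
    attr(x, "iterations") <- 0L
    attr(x, "missing_fraction") <- 0
    return(x)
  }
  if (frac >= 0.5) stop("more than half of the cells are missing")
  xc <- x
  cm <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) xc[miss[, j], j] <- cm[j]
  inc_rows <- which(rowSums(miss) > 0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    mu <- colMeans(xc)
    sv <- svd(sweep(xc, 2, mu), nu = 0, nv = n_components)
    P <- sv$v
    old <- xc[miss]
    for (i in inc_rows) {
      obs <- !miss[i, ]
      Po <- P[obs, , drop = FALSE]
      xi <- xc[i, obs] - mu[obs]
      sc <- tryCatch(solve(crossprod(Po), crossprod(Po, xi)),
                     error = function(e) NULL)
      if (is.null(sc)) next
      pred <- P[!obs, , drop = FALSE] %*% sc + mu[!obs]
      xc[i, !obs] <- pred
    }
    if (max(abs(xc[miss] - old)) < tol) {
      converged <- TRUE
      break
    }
  }
  attr(xc, "converged") <- converged
  attr(xc, "iterations") <- it
  attr(xc, "missing_fraction") <- frac
  xc
}

#' Assemble the analysis-ready cohort matrix
#'
#' Full path from raw per-epoch observations to the matrix the regression
#' models consume: baseline normalization, within-participant z-scoring,
#' then TSR imputation of whatever cells the extraction flagged missing.
#'
#' @param raw Output of [extract_feature_matrix()] or
#'   [simulate_feature_matrix()].
#' @param params An [analysis_params()] list.
#' @return A data.frame of analysis rows with complete features and
#'   z-scored labels; attribute `imputation` carries convergence details.
#' @export
assemble_cohort_matrix <- function(raw, params = analysis_params()) {
  norm <- baseline_normalize(raw, params$baseline_method)
  z <- zscore_within_participant(norm)
  feats <- feature_names()
  fm <- as.matrix(z[feats])
  if (anyNA(fm)) {
    fm <- impute_tsr(fm, params$tsr_ncomp, params$tsr_max_iter, params$tsr_tol)
    z[feats] <- fm[, feats]
    attr(z, "imputation") <- attributes(fm)[c("converged", "iterations",
                                              "missing_fraction")]
  } else {
    attr(z, "imputation") <- list(converged = TRUE, iterations = 0L,
                                  missing_fraction = 0)
  }
  z
}

#' Run the whole extraction pipeline on a synthetic cohort
#'
#' Segments the cohort's recordings, extracts the 19 features per epoch,
#' and assembles the analysis matrix.
#'
#' @param cohort A [simulate_cohort()] result with recordings.
#' @param params An [analysis_params()] list.
#' @return As [assemble_cohort_matrix()].
#' @export
build_cohort_matrix <- function(cohort, params = analysis_params()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$recordings))
    stop("cohort was simulated without signals; use simulate_feature_matrix")
  slices <- segment_epochs(cohort$recordings, cohort$schedule)
  raw <- extract_feature_matrix(slices, cohort$labels, params)
  assemble_cohort_matrix(raw, params)
}
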