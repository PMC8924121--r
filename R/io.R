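# Plain-text interchange and reproducible runs --------------------------------
# One CSV per channel (`t_s,value`), a schedule CSV, a labels CSV, a
# ground-truth sidecar, a feature TSV, and a manifest recording the seed and
# a hash of the configuration. These writers/readers plus the drivers under
# analysis/ are the command-line surface of the package.

#' Write a synthetic cohort to a directory of CSV files
#'
#' Writes `<participant>_ecg.csv` / `<participant>_gsr.csv` (columns
#' `t_s,value`), `schedule.csv`, `labels.csv`, a `ground_truth.csv`
#' sidecar (synthetic generator state: latent anxiety, true tonic means,
#' true mean RR), and `manifest.txt` with the seed and a configuration
#' hash.
#'
#' @param cohort A [simulate_cohort()] result (with signals).
#' @param dir Output directory.
#' @param force Overwrite an existing non-empty directory (default FALSE).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir, force = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$recordings)) stop("cohort has no recordings to write")
  if (dir.exists(dir) && length(dir(dir)) > 0 && !force)
    stop(sprintf("directory %s is not empty (use force = TRUE)", dir))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pid in names(cohort$recordings)) {
    for (ch in c("ecg", "gsr")) {
      rec <- cohort$recordings[[pid]][[ch]]
      write.csv(data.frame(t_s = recording_times(rec), value = rec$samples),
                file.path(dir, sprintf("%s_%s.csv", pid, ch)),
                row.names = FALSE)
    }
  }
  write.csv(cohort$schedule, file.path(dir, "schedule.csv"), row.names = FALSE)
  write.csv(cohort$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  writeLines(c(sprintf("seed: %d", cohort$seed),
               sprintf("epoch_s: %g", cohort$epoch_s),
               sprintf("fs: %g", cohort$fs),
               sprintf("config_hash: %s", config_hash(cohort$effects))),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Read a cohort back from CSV files
#'
#' Inverse of [write_cohort_csv()] (the effect configuration itself is not
#' round-tripped; the manifest records its hash).
#'
#' @param dir Directory written by [write_cohort_csv()].
#' @return A list with `recordings`, `schedule`, `labels`, `truth`.
#' @export
read_cohort_csv <- function(dir) {
  schedule <- read.csv(file.path(dir, "schedule.csv"))
  labels <- read.csv(file.path(dir, "labels.csv"))
  truth_path <- file.path(dir, "ground_truth.csv")
  truth <- if (file.exists(truth_path)) read.csv(truth_path) else NULL
  recs <- list()
  for (pid in unique(schedule$participant)) {
    chans <- list()
    for (ch in c("ecg", "gsr")) {
      path <- file.path(dir, sprintf("%s_%s.csv", pid, ch))
      if (!file.exists(path)) stop(sprintf("missing channel file: %s", path))
      df <- read.csv(path)
      fs <- 1 / median(diff(df$t_s))
      chans[[ch]] <- new_recording(df$value, round(fs), ch, t0 = df$t_s[1])
    }
    recs[[pid]] <- chans
  }
  list(recordings = recs, schedule = schedule, labels = labels, truth = truth)
}

#' Hash a configuration object
#'
#' Deterministic md5 of the deparsed configuration, used in run manifests.
#'
#' @param cfg Any R object.
#' @return Hex string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg, control = "exact"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the complete analysis and write its output tables
#'
#' Ties the stages together for one reproducible run: assemble the matrix
#' (from recordings or a raw feature table), screen features against the
#' label, run LOSO regression for the requested family and feature set,
#' and write `features.tsv`, `correlations.tsv`, `metrics.tsv`,
#' `importance.tsv` and `run_log.txt` under `out_dir`.
#'
#' @param raw Raw observation table ([extract_feature_matrix()] /
#'   [simulate_feature_matrix()] output).
#' @param out_dir Output directory (created if needed).
#' @param family,feature_set Passed to [run_loso()].
#' @param params An [analysis_params()] list.
#' @param seed Integer seed.
#' @return List with `matrix`, `correlations`, `model`, `importance`,
#'   invisibly.
#' @export
run_analysis <- function(raw, out_dir, family = "lasso", feature_set = "all",
                         params = analysis_params(), seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mat <- assemble_cohort_matrix(raw, params)
  feats <- feature_names()
  cors <- feature_correlations(mat[feats], mat$stai_s_norm)
  mod <- run_loso(mat[feats], mat$stai_s_norm, mat$participant,
                  family = family, feature_set = feature_set, seed = seed)
  imp <- predictor_importance(mod)
  tsv <- function(df, name) write.table(
    df, file.path(out_dir, name), sep = "\t", row.names = FALSE, quote = FALSE)
  tsv(mat, "features.tsv")
  tsv(as.data.frame(cors), "correlations.tsv")
  tsv(data.frame(metric = names(mod$metrics), value = unname(mod$metrics)),
      "metrics.tsv")
  tsv(imp, "importance.tsv")
  writeLines(c(sprintf("seed: %d", seed),
               sprintf("family: %s  feature_set: %s", family, feature_set),
               sprintf("rows: %d  features: %d", nrow(mat), length(feats)),
               sprintf("missing fraction before imputation: %.4f",
                       attr(mat, "imputation")$missing_fraction),
               sprintf("params_hash: %s", config_hash(params)),
               sprintf("r(pred, actual): %.4f", mod$correlation$r)),
             file.path(out_dir, "run_log.txt"))
  invisible(list(matrix = mat, correlations = cors, model = mod,
                 importance = imp))
}
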