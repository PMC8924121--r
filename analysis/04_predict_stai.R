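#!/usr/bin/env Rscript
# Stage 4 — leave-one-subject-out prediction of state anxiety.
#
# Fits the four regression families (linear, SVR, lasso, bagged trees) to
# the assembled matrix under LOSO validation, for the three feature sets
# (all 19, VAD only, physiological only), and reports pooled out-of-fold
# metrics, the predicted-vs-actual correlation, and the lasso predictor-
# importance ranking. Reads results/features.tsv; writes model_metrics.tsv
# and importance.tsv.

library(staitrack)

seed <- 1
mat <- read.csv("results/features.tsv", sep = "\t")
x <- mat[feature_names()]
y <- mat$stai_s_norm
ids <- mat$participant

rows <- list()
for (fam in c("linear", "svr", "lasso", "tree_ensemble")) {
  for (fs in c("all", "vad_only", "physio_only")) {
    m <- run_loso(x, y, ids, family = fam, feature_set = fs, seed = seed)
    rows[[paste(fam, fs)]] <- data.frame(
      family = fam, feature_set = fs,
      mae = m$metrics["mae"], rmse = m$metrics["rmse"],
      r2 = m$metrics["r2"], adj_r2 = m$metrics["adj_r2"],
      r = m$correlation$r, p_adj = m$correlation$p_adj)
  }
}
metrics <- do.call(rbind, rows)
rownames(metrics) <- NULL
write.table(metrics, "results/model_metrics.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("LOSO performance by family and feature set:\n")
print(transform(metrics, mae = round(mae, 3), rmse = round(rmse, 3),
                r2 = round(r2, 3), adj_r2 = round(adj_r2, 3),
                r = round(r, 4), p_adj = signif(p_adj, 3)),
      row.names = FALSE)

best <- run_loso(x, y, ids, family = "lasso", feature_set = "all",
                 seed = seed)
imp <- predictor_importance(best)
write.table(imp, "results/importance.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("\nLasso predictor importance (mean |beta| across folds, SD as error bar):\n")
print(head(transform(imp, mean_abs_beta = round(mean_abs_beta, 4),
                     sd_beta = round(sd_beta, 4)), 10), row.names = FALSE)
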