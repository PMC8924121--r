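#!/usr/bin/env Rscript
# Stage 3 — univariate statistics.
#
# (a) One-tailed paired t-tests (Bonferroni-corrected across the three task
#     conditions) asking whether STAI-S rises from pre- to post-task, on
#     label-level cohorts simulated under conditions with and without an
#     anxiety-induction effect.
# (b) Pearson correlation of each of the 19 features with the z-scored
#     STAI-S label on the assembled matrix, Benjamini-Hochberg corrected.
#
# Reads results/features.tsv from stage 2; writes correlations.tsv and
# ttests.tsv.

library(staitrack)

seed <- 1
mat <- read.csv("results/features.tsv", sep = "\t")

ct <- feature_correlations(mat[feature_names()], mat$stai_s_norm)
write.table(as.data.frame(ct), "results/correlations.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
sig <- subset(as.data.frame(ct), significant)
cat("Features significantly correlated with STAI-S (BH-FDR < 0.05):\n")
print(sig[order(-abs(sig$r)), c("feature", "r", "df", "p_adj")],
      row.names = FALSE)

## pre/post paired t-tests on simulated induction conditions: the pre score
## is the baseline-epoch STAI-S, the post score an epoch under raised (task)
## or unchanged (control) latent anxiety
set.seed(seed + 3)
n <- 28
fx <- effect_config()
pre_anx <- runif(n, 0.2, 0.5)
mk_stai <- function(a) pmin(80, pmax(20, fx$stai_intercept +
                                       fx$stai_slope * a + rnorm(n, 0, fx$stai_sd)))
rows <- list()
for (cond in c("control", "induction_mild", "induction_strong")) {
  shift <- switch(cond, control = 0, induction_mild = 0.15,
                  induction_strong = 0.3)
  pre <- mk_stai(pre_anx)
  post <- mk_stai(pmin(1, pre_anx + shift))
  tt <- paired_ttest_one_tailed(pre, post, n_comparisons = 3)
  rows[[cond]] <- data.frame(condition = cond, n = n, t = tt$t, df = tt$df,
                             mean_diff = tt$mean_diff, p_adj = tt$p_adj)
}
tests <- do.call(rbind, rows)
write.table(tests, "results/ttests.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("\nPre/post STAI-S paired t-tests (one-tailed, Bonferroni x3):\n")
print(tests, row.names = FALSE)
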