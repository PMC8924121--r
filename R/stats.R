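# Univariate statistics: paired t-tests and feature screening -----------------

#' One-tailed paired t-test for an increase, Bonferroni-corrected
#'
#' Tests whether `post` exceeds `pre` (t on the differences `post - pre`,
#' df = n - 1, upper-tail p), with the p-value multiplied by
#' `n_comparisons` and capped at 1.
#'
#' @param pre,post Equal-length paired score vectors (n >= 2).
#' @param n_comparisons Bonferroni multiplier (default 3, one per task
#'   condition).
#' @return List `t`, `df`, `p_raw`, `p_adj`, `mean_diff`, `undefined`
#'   (TRUE when the differences have zero variance).
#' @export
paired_ttest_one_tailed <- function(pre, post, n_comparisons = 3) {
  stopifnot(length(pre) == length(post), length(pre) >= 2)
  d <- post - pre
  n <- length(d)
  s <- sd(d)
  if (!is.finite(s) || s == 0)
    return(list(t = NA_real_, df = n - 1L, p_raw = NA_real_,
                p_adj = NA_real_, mean_diff = mean(d), undefined = TRUE))
  t_stat <- mean(d) / (s / sqrt(n))
  p <- pt(t_stat, df = n - 1, lower.tail = FALSE)
  list(t = t_stat, df = n - 1L, p_raw = p,
       p_adj = min(1, p * n_comparisons), mean_diff = mean(d),
       undefined = FALSE)
}

#' Per-feature Pearson correlations with the label, FDR-corrected
#'
#' Pearson correlation of each feature column with the (z-scored STAI-S)
#' label, with Benjamini-Hochberg adjustment across the tested features.
#' Constant features are reported with `r = NA` and excluded from the
#' adjustment.
#'
#' @param x Feature matrix or data.frame of numeric columns (no missing
#'   values; impute first).
#' @param labels Numeric label vector, one per row.
#' @param alpha Significance level for the flag column (default 0.05).
#' @return A data.frame of class `correlation_table`: `feature`, `r`, `df`,
#'   `p_raw`, `p_adj`, `significant`.
#' @export
feature_correlations <- function(x, labels, alpha = 0.05) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels))
  if (anyNA(x) || anyNA(labels))
    stop("missing values must be imputed before correlation screening")
  n <- nrow(x)
  res <- data.frame(feature = colnames(x), r = NA_real_, df = n - 2L,
                    p_raw = NA_real_, p_adj = NA_real_, significant = FALSE)
  for (j in seq_len(ncol(x))) {
    if (sd(x[, j]) == 0 || sd(labels) == 0) next
    ct <- cor.test(x[, j], labels, method = "pearson")
    res$r[j] <- unname(ct$estimate)
    res$p_raw[j] <- ct$p.value
  }
  ok <- !is.na(res$p_raw)
  res$p_adj[ok] <- p.adjust(res$p_raw[ok], method = "BH")
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  attr(res, "excluded") <- res$feature[!ok]
  class(res) <- c("correlation_table", class(res))
  res
}
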