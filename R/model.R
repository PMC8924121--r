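# Leave-one-subject-out regression of state anxiety ---------------------------

#' Leave-one-subject-out folds
#'
#' One fold per participant: the test set is exactly that participant's
#' rows, the training set everyone else's. Folds partition the rows; any
#' overlap is an internal error (leakage guard).
#'
#' @param participant_ids Vector of participant ids, one per row.
#' @return List of `list(participant, train, test)` row-index pairs.
#' @export
loso_splits <- function(participant_ids) {
  ids <- unique(participant_ids)
  if (length(ids) < 2) stop("need at least 2 participants")
  folds <- lapply(ids, function(id) {
    test <- which(participant_ids == id)
    list(participant = id, train = which(participant_ids != id), test = test)
  })
  covered <- sort(unlist(lapply(folds, `[[`, "test")))
  if (!identical(covered, seq_along(participant_ids)))
    stop("internal error: folds do not partition the rows")
  folds
}

#' Fit one regression family and predict a held-out fold
#'
#' Families: `"linear"` (least squares; a singular design falls back to a
#' tiny ridge penalty, flagged), `"lasso"` (L1 penalty chosen by inner
#' 5-fold cross-validation restricted to the training rows), `"svr"`
#' (epsilon-SVR, RBF kernel), `"tree_ensemble"` (bagged regression trees,
#' 100 trees). For the linear and lasso families the `beta` slot holds the
#' fitted coefficients; for SVR and the tree ensemble it holds permutation
#' importances (signless), so that the Fig.-style ranking by `|beta|`
#' remains comparable across families.
#'
#' @param family One of `"linear"`, `"svr"`, `"lasso"`, `"tree_ensemble"`.
#' @param x_train,y_train Training features (matrix) and labels.
#' @param x_test Features to predict.
#' @param seed Integer seed making the fit deterministic.
#' @return List `pred` (length `nrow(x_test)`), `beta` (named by feature),
#'   `flags` (character).
#' @export
fit_predict <- function(family = c("linear", "svr", "lasso", "tree_ensemble"),
                        x_train, y_train, x_test, seed = 1) {
  family <- match.arg(family)
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test, ncol = ncol(x_train))
  stopifnot(identical(colnames(x_train), colnames(x_test)))
  if (anyNA(x_train) || anyNA(y_train) || anyNA(x_test))
    stop("missing values must be imputed before model fitting")
  set.seed(seed)
  flags <- character(0)
  feats <- colnames(x_train)
  if (family == "linear") {
    X <- cbind(`(Intercept)` = 1, x_train)
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) {
      flags <- c(flags, "ridge_fallback")
      cf <- solve(crossprod(X) + 1e-6 * diag(ncol(X)), crossprod(X, y_train))
    } else {
      cf <- qr.coef(qr_x, y_train)
    }
    pred <- as.numeric(cbind(1, x_test) %*% cf)
    beta <- setNames(as.numeric(cf[-1]), feats)
  } else if (family == "lasso") {
    foldid <- sample(rep_len(1:5, nrow(x_train)))
    cv <- glmnet::cv.glmnet(x_train, y_train, alpha = 1, foldid = foldid)
    fit <- glmnet::glmnet(x_train, y_train, alpha = 1, lambda = cv$lambda.min)
    pred <- as.numeric(predict(fit, x_test))
    beta <- setNames(as.numeric(coef(fit))[-1], feats)
  } else if (family == "svr") {
    fit <- e1071::svm(x_train, y_train, kernel = "radial", type = "eps-regression")
    pred <- as.numeric(predict(fit, x_test))
    beta <- .permutation_importance(function(xx) as.numeric(predict(fit, xx)),
                                    x_train, y_train)
  } else {
    fit <- randomForest::randomForest(x_train, y_train, ntree = 100,
                                      mtry = ncol(x_train))
    pred <- as.numeric(predict(fit, x_test))
    beta <- .permutation_importance(function(xx) as.numeric(predict(fit, xx)),
                                    x_train, y_train)
  }
  list(pred = pred, beta = beta, flags = flags)
}

# increase in training MSE when one feature is permuted (mean of 5 shuffles)
.permutation_importance <- function(predict_fn, x, y, n_rep = 5) {
  base <- mean((predict_fn(x) - y)^2)
  imp <- vapply(seq_len(ncol(x)), function(j) {
    d <- vapply(seq_len(n_rep), function(r) {
      xp <- x
      xp[, j] <- sample(xp[, j])
      mean((predict_fn(xp) - y)^2) - base
    }, numeric(1))
    mean(d)
  }, numeric(1))
  setNames(pmax(imp, 0), colnames(x))
}

#' Regression metrics on pooled out-of-fold predictions
#'
#' @param pred,actual Equal-length numeric vectors (n >= 3).
#' @param n_features Number of features `p` entering the adjusted R^2
#'   multiplier `(n - 1) / (n - p - 1)`.
#' @return Named vector `mae`, `rmse`, `r2`, `adj_r2` (`adj_r2` is NA when
#'   `n - p - 1 <= 0`).
#' @export
evaluate_predictions <- function(pred, actual, n_features) {
  stopifnot(length(pred) == length(actual), length(pred) >= 3)
  n <- length(pred)
  err <- pred - actual
  r2 <- 1 - sum(err^2) / sum((actual - mean(actual))^2)
  adj <- if (n - n_features - 1 > 0)
    1 - (1 - r2) * (n - 1) / (n - n_features - 1) else NA_real_
  c(mae = mean(abs(err)), rmse = sqrt(mean(err^2)), r2 = r2, adj_r2 = adj)
}

#' Pearson correlation between predicted and actual scores
#'
#' @param pred,actual Equal-length vectors (n >= 3).
#' @param n_comparisons Bonferroni multiplier for the p-value (default 1).
#' @return List `r`, `p_raw`, `p_adj` (capped at 1), `df`; `r` is NA with
#'   flag `undefined` when either vector has zero variance.
#' @export
predicted_actual_correlation <- function(pred, actual, n_comparisons = 1) {
  stopifnot(length(pred) == length(actual), length(pred) >= 3)
  if (sd(pred) == 0 || sd(actual) == 0)
    return(list(r = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
                df = length(pred) - 2L, undefined = TRUE))
  ct <- cor.test(pred, actual, method = "pearson")
  list(r = unname(ct$estimate), p_raw = ct$p.value,
       p_adj = min(1, ct$p.value * n_comparisons),
       df = unname(ct$parameter), undefined = FALSE)
}

#' Run a full leave-one-subject-out evaluation
#'
#' Fits the requested family once per fold, pools the out-of-fold
#' predictions, and reports metrics, the predicted-vs-actual correlation
#' and the per-fold coefficient table.
#'
#' @param x Feature matrix (rows = observations).
#' @param y Label vector (z-scored STAI-S).
#' @param participant_ids One id per row.
#' @param family Model family, see [fit_predict()].
#' @param feature_set `"all"`, `"vad_only"` or `"physio_only"` — selects
#'   the canonical feature subset before fitting.
#' @param seed Integer seed.
#' @return An object of class `model_result`: `pred` (pooled, row order
#'   preserved), `metrics`, `correlation`, `beta` (folds x features),
#'   `folds`, `family`, `feature_set`.
#' @export
run_loso <- function(x, y, participant_ids,
                     family = c("lasso", "linear", "svr", "tree_ensemble"),
                     feature_set = c("all", "vad_only", "physio_only"),
                     seed = 1) {
  family <- match.arg(family)
  feature_set <- match.arg(feature_set)
  x <- as.matrix(x)
  if (feature_set != "all") {
    keep <- switch(feature_set,
                   vad_only = c("valence", "arousal", "dominance"),
                   physio_only = c(hrv_feature_names(), "scl"))
    x <- x[, intersect(keep, colnames(x)), drop = FALSE]
  }
  folds <- loso_splits(participant_ids)
  pred <- rep(NA_real_, length(y))
  betas <- matrix(NA_real_, nrow = length(folds), ncol = ncol(x),
                  dimnames = list(vapply(folds, `[[`, "", "participant"),
                                  colnames(x)))
  for (k in seq_along(folds)) {
    f <- folds[[k]]
    fit <- fit_predict(family, x[f$train, , drop = FALSE], y[f$train],
                       x[f$test, , drop = FALSE], seed = seed + k)
    pred[f$test] <- fit$pred
    betas[k, ] <- fit$beta
  }
  stopifnot(!anyNA(pred))  # every row predicted exactly once
  structure(list(pred = pred, actual = y,
                 metrics = evaluate_predictions(pred, y, ncol(x)),
                 correlation = predicted_actual_correlation(pred, y),
                 beta = betas, folds = folds,
                 family = family, feature_set = feature_set, seed = seed),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result: %s on %s features, %d folds>\n",
              x$family, x$feature_set, nrow(x$beta)))
  cat(sprintf("  r(pred, actual) = %.4f (p_adj = %.3g)\n",
              x$correlation$r, x$correlation$p_adj))
  print(round(x$metrics, 4))
  invisible(x)
}

#' Predictor importance ranking across folds
#'
#' Features sorted by the mean absolute coefficient (or permutation
#' importance) across folds, with the SD across folds as the error bar.
#' Features that are zero in every fold are reported as excluded.
#'
#' @param result A `model_result` (or a folds x features beta matrix).
#' @return Data frame `feature`, `mean_abs_beta`, `sd_beta`, `excluded`,
#'   sorted by `mean_abs_beta` descending.
#' @export
predictor_importance <- function(result) {
  b <- if (inherits(result, "model_result")) result$beta else as.matrix(result)
  if (nrow(b) < 2) stop("need at least 2 folds")
  df <- data.frame(feature = colnames(b),
                   mean_abs_beta = colMeans(abs(b)),
                   sd_beta = apply(b, 2, sd),
                   excluded = apply(b, 2, function(v) all(v == 0)))
  df <- df[order(-df$mean_abs_beta), ]
  rownames(df) <- NULL
  df
}
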