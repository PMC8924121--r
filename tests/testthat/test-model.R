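make_linear_data <- function(n_participants = 10, rows_per = 3, p = 5,
                             noise = 0, seed = 1) {
  set.seed(seed)
  n <- n_participants * rows_per
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  beta <- seq_len(p)
  y <- as.numeric(x %*% beta) + rnorm(n, 0, noise)
  list(x = x, y = y,
       ids = rep(sprintf("S%02d", seq_len(n_participants)), each = rows_per))
}

test_that("LOSO folds partition rows with one participant per test fold", {
  ids <- rep(sprintf("P%02d", 1:25), each = 3)
  folds <- loso_splits(ids)
  expect_length(folds, 25)
  test_rows <- unlist(lapply(folds, `[[`, "test"))
  expect_equal(sort(test_rows), seq_along(ids))       # disjoint cover
  for (f in folds)
    expect_false(f$participant %in% ids[f$train])     # leakage guard
  expect_error(loso_splits(rep("A", 5)), "at least 2")
})

test_that("lasso recovers a noiseless linear rule out of fold", {
  d <- make_linear_data(noise = 0)
  folds <- loso_splits(d$ids)
  pred <- rep(NA_real_, length(d$y))
  for (f in folds) {
    fit <- fit_predict("lasso", d$x[f$train, ], d$y[f$train],
                       d$x[f$test, , drop = FALSE], seed = 1)
    pred[f$test] <- fit$pred
  }
  expect_gt(cor(pred, d$y), 0.99)
})

test_that("permuted labels give out-of-fold correlations centred on zero
           and far below the true-label fit", {
  d <- make_linear_data(n_participants = 25, noise = 0, seed = 2)
  set.seed(3)
  rs <- replicate(20, {
    yp <- sample(d$y)
    run_loso(d$x, yp, d$ids, family = "linear", seed = 1)$correlation$r
  })
  expect_lt(abs(mean(rs)), 0.15)
  real <- run_loso(d$x, d$y, d$ids, family = "linear",
                   seed = 1)$correlation$r
  expect_true(all(rs < real))
})

test_that("an all-zero feature gets a zero lasso coefficient", {
  d <- make_linear_data(noise = 0.1, seed = 4)
  x <- cbind(d$x, dead = 0)
  fit <- fit_predict("lasso", x, d$y, x[1:2, , drop = FALSE], seed = 1)
  expect_equal(unname(fit$beta["dead"]), 0)
})

test_that("a singular design falls back to ridge with a flag", {
  d <- make_linear_data(seed = 5)
  x <- cbind(d$x, dup = d$x[, 1])
  fit <- fit_predict("linear", x, d$y, x[1:2, , drop = FALSE], seed = 1)
  expect_true("ridge_fallback" %in% fit$flags)
  expect_true(all(is.finite(fit$pred)))
})

test_that("metrics follow their definitions", {
  y <- c(1, 2, 3, 4, 5)
  perfect <- evaluate_predictions(y, y, n_features = 2)
  expect_equal(unname(perfect), c(0, 0, 1, 1))
  at_mean <- evaluate_predictions(rep(mean(y), 5), y, n_features = 1)
  expect_equal(unname(at_mean["r2"]), 0)
  expect_lt(unname(at_mean["adj_r2"]), 0)
  # the study-scale multiplier: n = 75, p = 19 -> (n-1)/(n-p-1) = 74/55
  set.seed(6)
  yy <- rnorm(75); pp <- yy + rnorm(75, 0, 0.5)
  m <- evaluate_predictions(pp, yy, n_features = 19)
  r2 <- unname(m["r2"])
  expect_equal(unname(m["adj_r2"]), 1 - (1 - r2) * 74 / 55, tolerance = 1e-12)
  expect_true(is.na(evaluate_predictions(pp[1:5], yy[1:5], 10)["adj_r2"]))
})

test_that("predicted-actual correlation handles the exact and degenerate
           cases", {
  y <- rnorm(10)
  expect_equal(predicted_actual_correlation(y, y)$r, 1)
  expect_equal(predicted_actual_correlation(-y, y)$r, -1)
  flat <- predicted_actual_correlation(rep(1, 10), y)
  expect_true(flat$undefined)
  capped <- predicted_actual_correlation(y + rnorm(10, 0, 10), y,
                                         n_comparisons = 1e6)
  expect_lte(capped$p_adj, 1)
})

test_that("importance ranks the dominant predictor first", {
  # arousal is the only strongly driven observable in this configuration
  fx <- effect_config(arousal_slope = 6, valence_slope = -0.5,
                      dominance_slope = -0.5, vad_sd = 0.2,
                      mean_rr_slope_ms = 0, hf_amp_slope_ms = 0,
                      scl_slope_us = 0.2)
  raw <- simulate_feature_matrix(25, 4, effects = fx, seed = 7)
  mat <- assemble_cohort_matrix(raw)
  mod <- run_loso(mat[feature_names()], mat$stai_s_norm, mat$participant,
                  family = "lasso", seed = 7)
  imp <- predictor_importance(mod)
  expect_equal(nrow(imp), 19)
  expect_equal(imp$feature[1], "arousal")
  b <- mod$beta; b[, "apen"] <- 0
  imp2 <- predictor_importance(b)
  expect_true(imp2$excluded[imp2$feature == "apen"])
  expect_equal(imp2$sd_beta[imp2$feature == "apen"], 0)
})

test_that("LOSO results are deterministic and leak-proof", {
  raw <- simulate_feature_matrix(8, 4, seed = 8)
  mat <- assemble_cohort_matrix(raw)
  args <- list(mat[feature_names()], mat$stai_s_norm, mat$participant)
  m1 <- do.call(run_loso, c(args, family = "svr", seed = 5))
  m2 <- do.call(run_loso, c(args, family = "svr", seed = 5))
  expect_identical(m1$pred, m2$pred)
  expect_identical(m1$metrics, m2$metrics)
  # a participant's own labels never reach their own fold's training set:
  # corrupting them leaves that fold's predictions untouched
  y2 <- mat$stai_s_norm
  sel <- mat$participant == "P03"
  y2[sel] <- rev(y2[sel]) + 5
  m3 <- run_loso(mat[feature_names()], y2, mat$participant,
                 family = "svr", seed = 5)
  expect_identical(m1$pred[sel], m3$pred[sel])
})

test_that("all four families run and the feature sets have the right width", {
  raw <- simulate_feature_matrix(6, 4, seed = 9)
  mat <- assemble_cohort_matrix(raw)
  for (fam in c("linear", "svr", "lasso", "tree_ensemble")) {
    m <- run_loso(mat[feature_names()], mat$stai_s_norm, mat$participant,
                  family = fam, seed = 2)
    expect_length(m$pred, nrow(mat))
    expect_true(all(is.finite(m$metrics[c("mae", "rmse", "r2")])))
  }
  m_vad <- run_loso(mat[feature_names()], mat$stai_s_norm, mat$participant,
                    family = "linear", feature_set = "vad_only", seed = 2)
  expect_equal(ncol(m_vad$beta), 3)
  m_phys <- run_loso(mat[feature_names()], mat$stai_s_norm, mat$participant,
                     family = "linear", feature_set = "physio_only", seed = 2)
  expect_equal(ncol(m_phys$beta), 16)
})
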