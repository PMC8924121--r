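Package: staitrack
Title: Dynamic Tracking of State Anxiety from Multi-Modal Psychophysiological Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An epoch-based pipeline for estimating state anxiety (STAI-S) from
    multi-modal recordings. Provides a seeded synthetic-cohort generator
    (ECG with known R peaks, skin conductance with tonic/phasic structure,
    dimensional emotion ratings, and STAI-S labels driven by a latent anxiety
    process), ECG cleaning with beat detection and relative-RR artifact
    rejection, fifteen heart-rate-variability features per epoch, tonic
    skin-conductance-level extraction by nonnegative deconvolution, assembly
    of a baseline-normalized within-participant z-scored feature matrix with
    iterative PCA (trimmed-scores) imputation, leave-one-subject-out
    regression with four model families, and the accompanying paired t-test
    and feature-correlation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    glmnet,
    e1071,
    randomForest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
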