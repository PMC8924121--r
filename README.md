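# staitrack

Epoch-based tracking of **state anxiety** from multi-modal
psychophysiological data.

Questionnaire instruments such as the state subscale of the State–Trait
Anxiety Inventory (STAI-S, 20 items, scored 20–80) measure anxiety "right
now" but cannot be administered more often than every few minutes.
Continuous recordings can: the ECG carries heart-rate-variability (HRV)
signatures of autonomic balance, electrodermal activity carries the tonic
skin conductance level (SCL), and momentary valence/arousal/dominance
ratings (VAD, 1–9) summarize the felt state. `staitrack` is for
psychophysiologists and affective-computing researchers who want a tested,
reproducible pipeline from raw 1000-Hz ECG/skin-conductance channels to a
leave-one-subject-out (LOSO) regression of STAI-S on 19 per-epoch features:

* 15 HRV features per epoch — mean RR, SDNN, the median and IQR of the
  distance to the centroid of the relative-RR return map, RMSSD, pNN50,
  TRI and TINN (1/128-s histogram bins), Poincaré SD1/SD2 and their ratio,
  LF (0.04–0.15 Hz) and HF (0.15–0.40 Hz) power and LF/HF, and approximate
  entropy ApEn(m = 2, r = 0.2·SD);
* the SCL — mean of the tonic component separated from phasic
  Bateman-shaped responses by nonnegative deconvolution;
* the three VAD ratings.

Per participant, the first rest epoch is a baseline: remaining epochs are
baseline-subtracted and z-scored within participant (features and label
alike), pooled across participants, and missing cells imputed by trimmed
scores regression (iterative PCA, 3 components, tol 1e-9). Four model
families (linear, SVR, lasso, bagged trees) are validated LOSO, with
pooled out-of-fold MAE, RMSE, R², adjusted R², the predicted-vs-actual
Pearson r, and a |β| importance ranking. A univariate layer provides
one-tailed paired t-tests (Bonferroni) and per-feature Pearson
correlations with Benjamini–Hochberg FDR control.

Because such raw recordings are typically available only on request, the
package ships a seeded synthetic-cohort generator (`simulate_cohort()`)
with full ground truth — latent anxiety, exact R-peak times, true tonic
traces — so every stage is validated by round-trip. See the methods
vignette (`vignettes/state-anxiety-tracking.Rmd`) for the model,
conventions and limitations.

## Worked example

The study-scale run (25 participants × 4 five-minute rest epochs of
1000-Hz ECG and skin conductance; about two minutes of compute):

```r
library(staitrack)

cohort <- simulate_cohort(seed = 1)          # defaults: 25 x 4 x 300 s
mat    <- build_cohort_matrix(cohort)        # segment -> features -> assemble
dim(as.matrix(mat[feature_names()]))
#> [1] 75 19

ct <- feature_correlations(mat[feature_names()], mat$stai_s_norm)
subset(as.data.frame(ct), feature %in% c("arousal", "valence", "scl"))[
  c("feature", "r", "df", "p_adj")]
#>    feature          r df        p_adj
#> 16     scl  0.6589763 73 1.244494e-09
#> 17 valence -0.5520304 73 4.900776e-07
#> 18 arousal  0.6174319 73 8.628468e-09

fit <- run_loso(mat[feature_names()], mat$stai_s_norm, mat$participant,
                family = "lasso", seed = 1)
fit
#> <model_result: lasso on all features, 25 folds>
#>   r(pred, actual) = 0.5336 (p_adj = 8.25e-07)
#>    mae   rmse     r2 adj_r2
#> 0.5625 0.6912 0.2829 0.0352
```

75 rows are the 25 participants' three post-baseline epochs. The
correlations recover the configured psychophysiology — arousal and SCL
rise with state anxiety, valence falls — and the pooled out-of-fold lasso
prediction correlates r ≈ 0.53 with the held-out z-scored STAI-S, in line
with what this design can support. (Out-of-fold numbers for other seeds
and families vary; `analysis/04_predict_stai.R` prints the full
family × feature-set table.)

## The analysis workflow

Numbered drivers under `analysis/` run the whole study and write tables to
`results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generates the cohort; writes labels/schedule/ground truth (and a small CSV demo of the signal interchange format under `scratch/`) |
| `02_extract_features.R` | full signal pipeline; writes `features_raw.tsv`, `features.tsv` |
| `03_univariate_stats.R` | feature–STAI-S correlations (BH-FDR) and pre/post paired t-tests; writes `correlations.tsv`, `ttests.tsv` |
| `04_predict_stai.R` | LOSO regression, all families × feature sets; writes `model_metrics.tsv`, `importance.tsv` |

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_extract_features.R
Rscript analysis/03_univariate_stats.R
Rscript analysis/04_predict_stai.R
```

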