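---
title: "Tracking state anxiety from multi-modal psychophysiological epochs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking state anxiety from multi-modal psychophysiological epochs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(staitrack)
```

## The problem and the model

Questionnaire measures of state anxiety (the STAI-S, a 20-item scale scored
20–80) have a temporal resolution of minutes to hours. Anxiety, however, is
accompanied by fast autonomic responses that continuous recordings capture:
heart-rate variability (HRV) from the ECG and the tonic skin conductance
level (SCL) from electrodermal activity, alongside momentary dimensional
emotion ratings of valence, arousal and dominance (VAD, 1–9). `staitrack`
implements an epoch-based pipeline that regresses STAI-S onto 19 such
features — 15 HRV features, SCL, and the three VAD ratings — and validates
the regression leave-one-subject-out (LOSO), so that a participant's own
epochs never inform the model that predicts them.

The analysis design it targets is a resting-state cohort: each participant
contributes four 5-minute rest epochs; the first is a baseline. Features
and STAI-S of the remaining epochs are normalized to that baseline,
z-scored within participant, and pooled: with 25 participants this yields
the canonical 75-observation × 19-feature matrix with a z-scored STAI-S
label per row.

Because the kind of raw recordings this pipeline consumes are typically
shareable only on request, the package carries a first-class synthetic
cohort generator whose ground truth (latent anxiety, exact R-peak times,
true tonic traces) makes every downstream stage testable by round-trip.

## The synthetic cohort

A latent anxiety level $a \in [0,1]$ evolves per participant as a random
walk across epochs (start $\sim U(0.2, 0.8)$, steps $N(0, 0.25)$, clipped).
Each observable is an affine function of $a$ plus Gaussian noise, with the
slope signs encoding the expected psychophysiology: arousal, SCL, heart
rate, and high-frequency RR modulation (hence RMSSD) rise with anxiety;
valence and dominance fall. STAI-S is generated on the raw 20–80 scale and
clipped, so the pipeline's own normalization is exercised downstream.

The signal layer realizes these parameters physically:

* **ECG** — beat-to-beat RR intervals
  $RR_i = \mu + A_{LF}\sin(2\pi f_{LF} t_i) + A_{HF}\sin(2\pi f_{HF} t_i) + \varepsilon_i$
  (defaults $f_{LF} = 0.1$ Hz, $f_{HF} = 0.25$ Hz), a Mexican-hat QRS-like
  spike of ≈80 ms width at each cumulative beat time, 0.25-Hz baseline
  wander, and white noise, at 1000 Hz. A parameter-free analytic spike
  suffices because beat detection only needs R-wave prominence; realistic
  PQRST morphology is deliberately out of scope.
* **Skin conductance** — a slowly varying tonic level plus phasic responses
  shaped by the unit-peak Bateman kernel
  $e^{-t/\tau_2} - e^{-t/\tau_1}$ ($\tau_1 = 0.75$ s rise,
  $\tau_2 = 2$ s decay, standard electrodermal values), Poisson-placed at 8
  events/min with exponentially distributed amplitudes (mean 0.4 µS), plus
  noise. Values are constrained to the 0.2–100 µS measuring range.

Effect magnitudes are free parameters of the design (`effect_config()`).
They were fixed once, when the generator was designed, so that the
feature–label correlations of the assembled matrix have the moderate to
strong magnitudes (|r| ≈ 0.4–0.7) and stable signs typical of this
paradigm; they were not revisited afterwards. What the generator does *not*
emulate: task-evoked ECG morphology changes, respiration, movement
artifacts beyond white noise, rater idiosyncrasies, or any nonlinearity in
the anxiety–observable coupling. Green tests therefore demonstrate that the
pipeline recovers the structure it assumes, not that real recordings meet
those assumptions.

## ECG path

1. **Trimmed moving average** (window 0.2 s, trim fraction 0.25 per tail):
   each sample is replaced by the mean of its centred window after
   discarding the `floor(0.25·W)` smallest and largest values; edge windows
   are truncated, never padded, to avoid fabricating samples. Because a
   25% trim of a 0.2-s window discards almost exactly the samples a QRS
   spike occupies, this filter is a *robust baseline estimator*: the
   detection signal is the z-scored residual `raw − baseline`
   (`preprocess_ecg()`), which removes wander and movement artifacts while
   leaving R peaks intact.
2. **Beat detection**: local maxima above an adaptive prominence threshold
   (half the 99th-percentile amplitude) with a refractory period of
   60000/220 ms — the RR interval of the fastest valid heart rate. Ties
   inside a refractory window keep the taller peak.
3. **RR validity and artifact rejection**: intervals outside 50–220 bpm are
   invalid. Relative RR, $rrr_i = 2(RR_{i+1}-RR_i)/(RR_{i+1}+RR_i)$, flags
   an interior interval as an artifact when **both** flanking transitions
   exceed 0.2 in magnitude (an ectopic or missed beat perturbs both of its
   transitions; its innocent neighbours only one), edge intervals on their
   single side. The cutoff is configurable; flagged intervals are excluded
   and the removed fraction reported.

## The fifteen HRV features

In frozen order (`hrv_feature_names()`): mean and SD of RR (ms); median and
IQR ("annular intensity") of the Euclidean distance to the centroid of the
relative-RR return map; RMSSD; pNN50 (successive differences > 50 ms); the
triangular index TRI and TINN from the RR histogram with 1/128-s bins
(the interpretation of "bin size 1/128" as 1/128 s is the only convention
under which TRI/TINN take their customary units); Poincaré SD1, SD2 and
their ratio; LF (0.04–0.15 Hz) and HF (0.15–0.40 Hz) power with LF/HF; and
approximate entropy.

Numerical conventions, fixed and documented:

* `sd_rr` uses the sample SD ($n-1$); SD1/SD2 are *population* SDs of the
  rotated return-map coordinates $(RR_{i+1} \mp RR_i)/\sqrt2$. Under that
  convention SD1 equals RMSSD$/\sqrt2$ exactly when the successive
  differences sum to zero, and a linearly ramping series has SD1 = 0.
* TINN fixes the triangle apex at the modal bin at modal height and
  exhaustively searches baseline endpoints on the bin grid (one empty bin
  of slack beyond each end), minimizing squared error; an exactly
  triangular histogram returns its base width. A single-bin histogram
  degenerates to TRI = 1, TINN = one bin width.
* The spectral features interpolate the tachogram with a natural cubic
  spline at 4 Hz, detrend linearly, and average Hann-windowed Welch
  segments of up to 60 s with 50% overlap. Epochs shorter than 50 s cannot
  resolve the LF band edge and are flagged low-confidence.
* ApEn uses the standard parameters $m = 2$, $r = 0.2\,\mathrm{SD}$, with
  self-matches included; a constant series returns 0 by convention.
* Any feature that cannot be computed is `NA` with a missing flag — never
  a silent `NaN`; an epoch with fewer than 10 cleaned intervals has its
  whole HRV vector flagged missing, which feeds the imputation stage.

## EDA path

The skin-conductance signal is lowpass-filtered at 5 Hz with an order-10
Butterworth applied forward–backward (zero phase, DC gain 1). The filter is
built as cascaded second-order sections — a single transfer function of
order 10 at a normalized cutoff of 0.005 is numerically unusable — with
odd-reflection padding long enough for the section transients to settle.
After filtering, the signal is decimated to 20 Hz (tonic dynamics are
sub-Hz; the 5-Hz lowpass has already served as the anti-alias filter) and
smoothed by an adaptive Gaussian window: a bank of fixed-width Gaussians
blended per sample by local slope, wide (support capped at 3 s) over flat
stretches and narrow at SCR onsets. The per-sample effective width is
returned for inspection.

`decompose_tonic()` separates tonic from phasic in the spirit of continuous
decomposition analysis, simplified to fixed default $\tau$ values because
only the tonic *mean* (SCL) is consumed downstream and that mean is robust
to $\tau$; the generator round trip is the acceptance surface for this
choice. Internally (at 10 Hz): a coarse tonic floor (smoothed running
minimum over 20 s) is subtracted; the residual is deconvolved against the
Bateman kernel by FISTA-projected nonnegative ridge-regularized least
squares (spectral division would be unstable on short epochs); tonic
anchors are placed at the quietest driver point of each 10-s window, valued
at the signal minus the reconstructed phasic; a natural spline through the
anchors, capped at the signal, is the tonic trace. SCL is its arithmetic
mean. If no quiescent stretch exists the tonic falls back to the smoothed
running minimum, flagged low-confidence. An SCL outside 0.2–100 µS is
flagged missing.

## Assembly, normalization, imputation

Epochs are half-open $[start, end)$ slices, so adjacent epochs share no
sample. Extraction failures become missingness, never errors, and the two
channels fail independently. Baseline normalization *subtracts* the first
epoch (features and STAI-S alike) — subtraction rather than a ratio because
a ratio is undefined for zero or negative baseline values of z-scale
quantities and composes badly with the subsequent z-score; a `"ratio"`
switch exists for sensitivity analyses. Within-participant z-scoring uses
the sample SD over each participant's three analysis rows; a zero-variance
feature becomes zeros, flagged.

Missing cells are imputed by trimmed scores regression (TSR): iterative
PCA with 3 components, up to 5000 iterations, tolerance 1e-9 on the largest
cell change (a `1e-10` setting is available in `analysis_params()`).
Missing cells start at column means; each iteration fits the principal
subspace of the completed matrix and re-predicts each incomplete row's
missing cells from scores regressed on its observed part. Observed cells
are never altered. The pipeline imputes on the normalized, z-scored matrix
(normalize → z-score → impute); whether to impute before or after
z-scoring is genuinely open, and this order keeps the imputation model on
the scale the regression consumes. The order is a consequence of the
assembly function, not a hidden constant.

## Regression and statistics

`loso_splits()` produces one fold per participant and verifies the folds
partition the rows — a leakage guard, since within-participant z-scoring
makes within-subject leakage especially attractive. Four families are
fitted per fold: ordinary least squares (ridge-jitter fallback on singular
designs, flagged), epsilon-SVR with an RBF kernel, the lasso with its
penalty chosen by inner 5-fold cross-validation restricted to the training
fold (no leakage, standard practice; the study design names the family but
no penalty), and bagged regression trees (100 trees). Metrics (MAE, RMSE,
R², adjusted R² with the $(n-1)/(n-p-1)$ multiplier) and the
predicted-vs-actual Pearson correlation are computed on the *pooled*
out-of-fold predictions, matching how a single predicted-vs-actual
correlation over all observations is conventionally reported. For the
linear families "beta" is the fitted coefficient; for SVR and trees the
same slot carries permutation importance, labelled as such, so the
`|beta|`-ranking remains comparable. The univariate layer provides the
one-tailed paired t-test (Bonferroni ×3, one per task condition) and
per-feature Pearson correlations with Benjamini–Hochberg adjustment — BH
being the default meaning of "FDR" in this literature.

## Problem sizes used by the tests

The test-suite and acceptance script sizes are the package's own choices:
the full-signal default cohort (25 × 4 × 300 s at 1000 Hz) is built once
per run; generator round trips use 20 seeds of 60-s ECG and 300-s skin
conductance fixtures (the latter at 100 Hz input — the decomposition runs
at 10 Hz regardless); model-stability checks across 10 seeds use the
label-level generator `simulate_feature_matrix()`, which emits the same
statistical structure without waveform synthesis, while the waveform route
is exercised by the single full cohort.

## Known limitations

* Beat detection is validated against the generator, not against a
  clinical annotation standard; real ECG with T-wave prominence or severe
  noise may need a different detector behind the same interface.
* The tonic/phasic separation fixes the Bateman constants; per-subject
  $\tau$ optimization and inter-impulse fitting of full CDA are not
  implemented.
* TINN is only approximately scale-equivariant (its bin grid is absolute,
  1/128 s), and on 75-observation cohorts the adjusted R² is a noisy
  quantity with $p = 19$.
* The feature-level generator draws the undriven HRV features as plausible
  noise; only the waveform route gives them their physiological couplings.
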