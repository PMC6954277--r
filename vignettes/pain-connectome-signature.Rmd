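---
title: "Predicting pain sensitivity from the resting-state connectome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting pain sensitivity from the resting-state connectome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(rpnsig)
```

# The problem

Individual sensitivity to pain varies widely and is usually measured with
quantitative sensory testing (QST): repeated thermal stimulation for heat
and cold pain thresholds (HPT, CPT) and pinprick staircases for the
mechanical pain threshold (MPT). `rpnsig` implements the full analysis
chain for predicting a composite QST-based pain-sensitivity score from
pain-free resting-state functional connectivity: threshold scoring, motion
quality control, regional-timeseries cleaning, partial-correlation
connectome estimation, a sparse predictive model with cross-validated
hyperparameter search, external application of the trained signature, and
permutation/bootstrap inference. A synthetic-cohort generator with a known
planted structure makes every stage testable without access to any real
cohort.

# Pain-sensitivity scoring

Single-modality thresholds follow the standard QST conventions:

* **Thermal (HPT, CPT)** — the protocol acquires 6 repetitions; the first
  is a test stimulus and is discarded, and the threshold is the arithmetic
  mean of the remaining temperatures (`thermal_pain_threshold()` accepts
  any number of trials at least 2).
* **Mechanical (MPT)** — the threshold is the log10 of the geometric mean
  force over the staircase runs (typically 5 ascending + 5 descending),
  i.e. the mean of `log10(force mN)`. MPT is stored and scored on the
  log10 scale throughout; base 10 is the convention used in the QST
  literature for these forces.
* **T50** — where tonic-stimulus ratings are available, the temperature
  producing a rating of 50/100 is interpolated from a least-squares
  second-order polynomial of rating on temperature. The fitted quadratic
  can have two roots at rating 50; `t50_from_ratings()` restricts
  candidates to the stimulated temperature range and, when both roots fall
  inside it, returns the larger (the ascending branch of the
  stimulus-response curve, which is the physiologically relevant one for
  increasing heat). A fit with no temperature dependence raises a
  degenerate-fit error rather than extrapolating.

The composite score z-transforms each threshold against reference
statistics, flips the sign of HPT and MPT (for these, *lower* thresholds
mean *higher* sensitivity), and averages:

$$\mathrm{score} = \frac{1}{|M|} \sum_{m \in M} s_m \frac{x_m - \mu_m}{\sigma_m},
\qquad s_m = \begin{cases}-1 & m \in \{\mathrm{HPT}, \mathrm{MPT}\}\\ +1 & m = \mathrm{CPT}\end{cases}$$

The reference statistics $(\mu_m, \sigma_m)$ are those of the *training*
population, also when scoring external cohorts — this keeps all cohorts on
one scale. The modality set $M$ defaults to all three but is configurable
(two-modality scores support robustness analyses); the output records
`n_modalities_used`.

Extreme-value screening compares each threshold to a normative 95%
percentile interval and excludes a subject only when at least **two** of
the three modalities are extreme. The normative intervals themselves come
from the QST reference literature and are deliberately not bundled: the
package ships a placeholder template
(`inst/extdata/normative_bounds_template.json`) and
`read_qst_bounds_json()` refuses to screen until real values are filled
in, so no analysis can silently run with fabricated norms.

# Motion quality control

Head motion is summarised per frame as Power's framewise displacement,

$$\mathrm{FD}_t = \sum_{k=1}^{3} |\Delta d_{t,k}| + r \sum_{k=1}^{3} |\Delta \theta_{t,k}|,$$

with backward differences, rotations converted to arc length on a sphere
of radius $r = 50$ mm (the standard convention), and $\mathrm{FD}_1 = 0$
so the series aligns with the frames. Frames with FD strictly above
0.15 mm are scrubbed; a frame exactly at the threshold is retained (the
rule is "FD > 0.15 mm"). Only the flagged frame is dropped — no neighbour
augmentation by default. Subjects are excluded when mean FD exceeds
0.15 mm or more than 30% of frames are scrubbed; the mean FD is computed
over **all** frames (before scrubbing), which is the more conservative
reading, and both exclusion reasons are always reported.

The Friston-24 nuisance expansion contains, per rigid-body parameter, the
parameter, its square, its backward difference (first row 0) and the
squared difference, in fixed block order `[p, p^2, dp, dp^2]`.

Motion-parameter files are read as 6 whitespace-delimited columns ordered
rotations (radians) then translations (mm) — the realignment-tool
convention — with a `col_order = "trans_first"` override for the other
dialect.

# Timeseries cleaning

Cleaning operates on regional (already parcellated) signals; all
voxel-level processing is out of scope. The driver applies, in fixed,
logged order:

1. **Nuisance regression**: OLS residuals per node against an intercept,
   the 6 leading CompCor components of a noise-region signal matrix, the
   Friston-24 block and a linear trend. A rank-deficient design warns and
   falls back to the pseudo-inverse; the residuals are identical for any
   solution of the normal equations.
2. **Bandpass 0.008–0.08 Hz**: an ideal Fourier-domain filter — frequency
   bins inside the band are kept, everything else including DC is zeroed.
   This mirrors the frequency-domain filters common in fMRI pipelines and
   is exactly idempotent. A zero-phase Butterworth alternative
   (`method = "butterworth"`, via the `signal` package) is exposed for
   users who prefer an IIR response.
3. **Censoring**: scrubbed frames are dropped after filtering (the
   conventional order); original frame indices are recorded. Filtering
   before censoring means residual motion artefacts can leak into
   neighbouring frames through the filter — a known interaction; spike
   attenuation upstream is the usual mitigation.

A caveat documented rather than solved: filtering regional averages is
only approximately equivalent to averaging filtered voxel signals when
masks vary, since masking breaks strict commutation of the two linear
operations.

CompCor components are the leading principal components of the
column-demeaned noise matrix, unit-normalised, ordered by explained
variance, with the sign fixed so each component's largest-magnitude
loading is positive (sign-deterministic output).

# Connectome estimation

Connectivity between the 122 regions plus the global grey-matter signal —
kept as a 123rd *node* rather than regressed out, so its couplings remain
inspectable — is the partial correlation computed from the precision
matrix $\Theta = \Sigma^{-1}$:

$$\mathrm{pcor}_{ij} = -\frac{\Theta_{ij}}{\sqrt{\Theta_{ii}\,\Theta_{jj}}}.$$

Partial correlations suppress indirect (chain-mediated) coupling that
inflates marginal correlations. The covariance $\hat\Sigma$ is the
Ledoit–Wolf shrinkage estimate by default — implemented in-package
(`ledoit_wolf_cov()`), shrinking toward a scaled identity with the
analytically optimal intensity — because the empirical covariance is
singular or ill-conditioned whenever frames do not comfortably exceed
nodes, which is the normal regime at 123 nodes. The `"empirical"`
estimator is exposed for oracle testing: with it, the matrix equals the
brute-force regression-residual partial correlation to machine precision.
No Fisher z-transform is applied to the features; raw partial correlations
enter the model. The diagonal is fixed at 0 and excluded from the feature
space.

The feature space is the upper triangle in row-major order over the fixed
node order (atlas regions ascending, global node last):
$123 \cdot 122 / 2 = 7503$ features, with the closed-form index map
`feature_index(i, j) = i(2n - i - 1)/2 + (j - i - 1)` (0-based). Module
reordering (`order_by_modules()`) exists for visualisation only; features
always use the original order, so indices are stable.

# The predictive pipeline

Training pipes three stages, always refitted together inside any
resampling loop:

1. **Robust scaling**: $(x - \mathrm{median}) / (Q_{75} - Q_{25})$ per
   feature, scale 1 where the IQR is 0. The (25, 75) quantile range is
   fixed.
2. **K-best selection**: keep the $K$ features with largest univariate
   $|r|$ with the target (identical ranking to the regression
   F-statistic at fixed $n$), ties broken deterministically by ascending
   feature index. This is implemented as a single selection step.
3. **Elastic net** minimising
   $$\frac{1}{2n} \lVert y - b - Xw\rVert^2 + \alpha\rho\lVert w\rVert_1
     + \frac{\alpha(1-\rho)}{2}\lVert w\rVert^2,$$
   intercept unpenalised. The solver is glmnet (whose objective matches
   this normalisation exactly, so printed $\alpha$ values are meaningful),
   followed by a cyclic coordinate-descent polish that iterates until the
   KKT subgradient residual is below $10^{-8}$ — `kkt_residual()`
   certifies any fit against the optimality conditions, and the test suite
   requires $< 10^{-4}$ everywhere. The polish matters: at small sample
   sizes the path solver alone can sit a few $10^{-3}$ away from the
   optimum in flat directions.

Hyperparameters $(K, \rho, \alpha)$ are selected by leave-one-subject-out
grid search minimising mean squared LOO error, with the default grid
$K = 10, 15, \ldots, 200$, $\rho \in \{0.1, 0.5, 0.7, 0.9, 0.95, 0.99,
0.999\}$, $\alpha \in \{0.001, 0.005, 0.01, 0.05, 0.1, 0.5\}$. Every fold
refits scaling, selection and regression on the $n-1$ training subjects —
no statistic ever sees the held-out subject. Ties are broken toward the
more parsimonious cell (smaller $K$, then larger $\alpha$, then smaller
$\rho$). Internal-validation metrics are computed from the pooled LOO
predictions at the selected cell; selecting hyperparameters on the same
folds makes these estimates mildly optimistic, which is why external
validation on untouched cohorts is the headline evidence.

`extract_signature()` stores one entry per non-zero weight together with
the training median and IQR of that feature and the intercept, making the
signature self-contained: external application is
$\hat y = b + \sum_e w_e (x_e - \mathrm{med}_e)/\mathrm{iqr}_e$. A
signature without scaler parameters (mode `"weights_only"`, e.g. the
packaged published signature, for which scalers and intercept were never
printed) yields the plain dot product $\sum_e w_e x_e$ — an affine-relative
score: correlations and rankings against such scores are meaningful,
absolute errors are not, and the result is flagged accordingly.

Prediction quality is summarised as MSE, MAE, explained variance
$1 - \mathrm{Var}(y - \hat y)/\mathrm{Var}(y)$ and Pearson r (reported as
`NA` when the prediction is constant; explained variance is still defined
and equals 0 there).

# Inference

**Metric permutation tests** permute the observed scores against fixed
predictions and count permutations at least as good (lower MSE, higher
explained variance, higher r), with the add-one estimator
$p = (1 + \#\,\mathrm{as\ good})/(n_\mathrm{perm} + 1)$, which can never
return 0. This is the external-validation construction; a full-refit mode
that reruns the entire cross-validated pipeline per permutation exists
behind the `refit` argument for internal validation, default off because
it multiplies cost by the permutation count.

**Bootstrap inference** draws B = 10000 samples of (subject, score) pairs
with replacement by default, refits the whole pipeline at fixed
hyperparameters, and summarises each feature *conditional on its K-best
selection in a sample*: selection frequency, percentile 95% CI of the
selected weights, and the two-sided sign-based p-value
$2\min(\#\{w \le 0\}, \#\{w \ge 0\})/\#\mathrm{selected}$, floored at
$1/\#\mathrm{selected}$. Conditioning on selection is our explicit
operationalisation of conditional coverage; selection frequencies are
always reported so unconditional summaries can be derived, and features
never selected report `NA` rather than a fabricated interval.

**Confound association** regresses the predicted score on one covariate
(dummy-coded with first-level reference when categorical; ordinal
covariates are treated as categorical by default), takes $R^2$ as the
statistic and permutes the covariate. Missing values are dropped pairwise
with the n used reported. No multiple-testing correction is applied across
covariates — the reported values are per-covariate and any correction is
left to the user.

All resampling records its seed and replicate count in the output.

# The synthetic-cohort generator

The generator emulates exactly the statistical structure the analysis
assumes: a latent trait per subject expressed both in the connectome and
in the QST thresholds.

* **Connectome side**: a base precision matrix (identity plus sparse
  background couplings, density 0.08, magnitude 0.12, and a mild coupling
  of every region to a global-like node) is shifted on the planted edges
  by `effect * trait` and diagonally loaded so the minimum eigenvalue
  stays at 0.05. Planting on the *precision* scale keeps
  positive-definiteness controllable; the induced partial-correlation
  effect is approximately `-effect * trait` at unit diagonal. Frames are
  drawn from the implied Gaussian and AR(1)-smoothed (coefficient 0.3,
  scaled to preserve the stationary covariance, so estimated partial
  correlations stay unbiased while their sampling noise increases
  realistically).
* **QST side**: each modality's latent is
  $z_m = \lambda s + \sqrt{1-\lambda^2}\,\varepsilon_m$ with trait loading
  $\lambda = 0.8$ by default, signs arranged so that higher trait means
  more sensitive in every modality, expanded into 6 noisy thermal
  repetitions (sd 0.6 °C) and 10 pinprick runs (sd 0.1 log10 mN) around
  reference statistics typical of forearm QST in young adults
  (HPT 44.6 ± 3.0 °C, CPT 12 ± 8 °C, MPT 1.81 ± 0.35 log10 mN).
* **Motion**: random-walk rigid-body parameters (translation step sd
  0.008 mm, rotation step sd 1e-4 rad — quiet enough that spike-free
  traces stay below the 0.15 mm threshold) plus Bernoulli displacement
  spikes of 0.5 mm, which exceed the scrubbing threshold by construction;
  the injected spike frames are returned as ground truth.

The default cohort — 20 regions + global node, 200 frames at TR 2.5 s,
60 training / 40 test subjects, 4 planted edges — is sized so the full
chain runs in minutes on one core while keeping the geometry of the real
problem (regions + global node, TR 2.5 s, n < p after selection). All
randomness derives from one root seed through per-subject substreams, so a
cohort can be extended without changing existing subjects and everything
is bit-for-bit reproducible from `(config, seed)`.

What the generator does **not** emulate: hemodynamic dynamics, scanner
drift and physiological noise, multi-site batch effects, non-Gaussian
signal, atlas misalignment. Passing tests on synthetic cohorts therefore
demonstrate the correctness and internal consistency of the estimators and
the absence of information leakage — not real-data effect sizes.

# Validation choices worth recording

* **Support recovery is evaluated in the elastic net's grouping regime**
  ($\rho = 0.5$, $\alpha = 0.1$). The four planted edges are all proxies
  of one latent trait and hence strongly mutually correlated; near-lasso
  settings ($\rho \to 1$) provably select a representative subset of
  correlated predictors rather than all of them, even when all four are
  univariately top-ranked and K-best selected. The ability to tune
  sparsity away from the lasso for exactly this reason is the motivation
  for using the elastic net in the first place. Prediction quality, by
  contrast, is reported wherever convenient, including at the published
  operating point ($K = 25$, $\rho = 0.999$, $\alpha = 0.005$).
* **No-leakage null** runs the full LOO grid search on label-permuted data
  (n = 40, 100 features, a 3 × 2 × 3 grid) over 20 replicates; the mean
  cross-validated explained variance must not exceed 0.05. Individual
  null replicates legitimately reach ~0.2 by chance — only the mean is
  constrained.
* **Permutation calibration** uses 1000 null replicates at 500
  permutations each, for both the metric test and the confound test, and
  requires the empirical type-I rate at the 0.05 level to land in
  [0.03, 0.07].
* **Numerical tolerances**: partial-correlation oracle agreement at
  $10^{-8}$; KKT residuals at $10^{-4}$ (achieved: ~$10^{-8}$);
  extract/apply round-trip at $10^{-10}$; bandpass in-band gain ≥ 0.99 and
  out-of-band ≤ 0.01 on 512-frame sinusoids. The in-band time-domain gain
  can slightly exceed 1 for non-bin-centred frequencies (Gibbs ringing of
  the ideal filter at the series edges); this is a property of brick-wall
  filtering, not an error.

# Known limitations

* The pipeline starts from regional timeseries; it cannot detect problems
  upstream of parcellation (registration failure, atlas mismatch).
* The ideal bandpass assumes stationarity across the series and introduces
  edge ringing on short series; the Butterworth alternative trades that
  for passband ripple and roll-off.
* Weights-only signatures (including the packaged published one) cannot
  produce absolutely scaled predictions; MSE/MAE against such scores are
  not meaningful, only correlation-type metrics are.
* Internal-validation metrics from pooled LOO predictions at the selected
  hyperparameters carry selection optimism; treat external validation as
  the primary evidence.

# A compact end-to-end run

```{r, eval = FALSE}
cfg <- synth_config(n_subjects = 60, seed = 1)
train <- generate_cohort(cfg)
x <- cohort_features(train)
y <- cohort_scores(train)$score

search <- loo_grid_search(x, y, hyperparam_grid(
  k_values = c(10, 25, 50), l1_ratios = c(0.5, 0.999),
  alphas = c(0.005, 0.05, 0.1)
))
glance(search)

fit <- fit_pipeline(x, y, search$best_hp)
sig <- extract_signature(fit, training_label = "synthetic study 1", seed = 1)

test <- generate_cohort(synth_config(n_subjects = 40, seed = 2))
pred <- apply_signature(sig, cohort_features(test))
prediction_metrics(cohort_scores(test)$score, pred$prediction)
```
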