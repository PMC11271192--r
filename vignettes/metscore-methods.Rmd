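---
title: "Methods: serum NMR risk scoring for metabolic syndrome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum NMR risk scoring for metabolic syndrome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metscore)
```

This vignette is the package's own account of its statistical methods:
the models, the parameters that matter, the numerical choices, what the
synthetic-cohort generator does and does not emulate, and the known
limitations.

## The problem

Metabolic syndrome (MetS) is defined by counting binary risk factors —
diabetes/impaired fasting glucose, obesity, dyslipidemia, hypertension —
which yields a coarse, definition-dependent label. Serum NMR panels
quantify 41 circulating metabolites (mmol/L) and 112 lipoprotein
classes and subclasses (mg/dL; particle numbers in nmol/L; ratios
dimensionless), a continuous molecular readout of the same physiology.
The package turns such a panel into a calibrated 0–1 risk score
(MetSCORE) and the supporting statistics.

Each sample carries a 4-bit profile `(diabetes, obesity, dyslipidemia,
hypertension)`; `encode_profile()` concatenates the bits, so `1110` is
a patient with diabetes, obesity and dyslipidemia but no hypertension.
The WHO rule — diabetes plus at least two of the other three — selects
exactly the profiles `{1011, 1101, 1110, 1111}`; other consensus
definitions reduce to other subsets of the 16 codes and can be
registered with `register_mets_definition()` (their code sets are user
input, not built in, since the package does not adjudicate between
definitions).

## Univariate profiling

For each variable, standardized to mean 0 and sample SD 1 (n − 1
denominator throughout the package), an ordinary least-squares model

```
x_std ~ profile + gender + age_group
```

is fit with `0000` as the reference profile. Each profile coefficient
is therefore an effect size in SD units. Assumptions and choices:

* Classical (homoskedastic) standard errors and two-sided t-tests;
  robust errors would be a defensible alternative but plain OLS is the
  conventional reading of an adjusted linear model.
* Age enters as an unordered categorical with boundaries 18, 25, 35,
  45, 55, 64, 70, 81, 105 years (the last interval closed) — the
  cohort-study strata; no spline, no interactions.
* Profiles absent from the data are dropped from the design rather
  than imputed; a rank-deficient design errors naming the aliased
  columns rather than silently dropping them.
* p-values are Benjamini–Hochberg adjusted **within each dataset
  type** (serum metabolites, serum lipoproteins, urine bins), pooling
  all profile contrasts of a family; significance means adjusted
  p < 0.05.

For display, `heatmap_matrix()` truncates effects to [−1, 1], orders
variables and profiles by complete-linkage Euclidean clustering of the
untruncated effect matrix, and stars cells at adjusted-p thresholds
0.05/0.01/0.001/0.0001. Truncation affects only the displayed matrix,
never the statistics.

## Variable selection

The cascade order is fixed and its provenance flags partition the
input variables:

1. **Manual discards** — particle-number lipoprotein parameters
   (correlation of one with the Apo-B parameters, only the units
   differ) and the EDTA-related serum signals; configurable regular
   expressions (`default_exclusion_patterns()`), with
   `reduced_model_exclusions()` additionally removing glucose and the
   HDL/dense-LDL clusters for a model uncorrelated from the molecular
   definitions of diabetes and dyslipidemia.
2. **Near-zero-variance filter** — discard iff the most-common to
   second-most-common frequency ratio exceeds 19 (95/5) *and* the
   unique-value fraction is below 10%; a constant vector has infinite
   ratio and is discarded. On continuous data with no duplicated
   values the filter short-circuits to keep.
3. **Clustering** — pairwise distance `1 − ρ_Spearman` (signed, so
   anti-correlated variables are not merged), average linkage, tree
   cut at 0.5 for serum and 0.85 for urine bins (bins are more
   strongly cross-correlated). Spearman makes the clustering invariant
   to monotone transforms of each variable. Variables are processed in
   name order so ties resolve deterministically.
4. **Effect filter** — keep variables with at least one profile
   contrast that is simultaneously significant and of absolute effect
   ≥ 0.5 SD (the conjunction is required in the same contrast).
5. **Representatives** — one per cluster: the argmax of the cumulative
   absolute effect over *all* profiles (summing only significant
   profiles was the other defensible reading; all profiles is used),
   ties broken by name.

An empty survivor set is an error advising threshold review — except
inside cross-validation and permutation replicates, where the fitting
function falls back to the top five cluster representatives per
dataset type by cumulative effect: a permuted-label replicate would
otherwise fail by construction, and the permutation analysis needs a
score from every replicate. The fallback never engages on informative
data at the default thresholds.

## The discriminant and its preprocessing

Inputs are concentrations, so the preprocessing is `log(x + offset)`
followed by autoscaling with the training means and SDs. The offset is
0 for strictly positive variables and half the smallest positive value
where zeros occur; negative inputs are an error. Taking logs turns a
unit change into an additive constant that centering removes, so the
model is invariant to each variable's units.

The discriminant is O-PLS-DA with one predictive and one orthogonal
component (the count is fixed by design, not tuned), fit by the
orthogonal-signal-correction scheme for a single centered binary
response y:

1. `w = X'y / ‖X'y‖`, `t = Xw`, loading `p = X't / t't`;
2. orthogonal weight `w_o = p − (w'p) w`, normalized; orthogonal score
   `t_o = X w_o`, loading `p_o`; deflate `X ← X − t_o p_o'`;
3. refit the predictive component on the filtered matrix.

With a single response the NIPALS weight step is closed form, so the
fit is deterministic and iteration-free; no random initialization
exists. For one response the predictive weight is unchanged by the
deflation (the orthogonal score is orthogonal to `X'y` by
construction), which makes `w ⊥ w_o` and `corr(t_pred, t_orth) = 0`
hold exactly rather than approximately. If no response-orthogonal
structured variation exists, `‖w_o‖` vanishes (threshold 1e-8) and the
model degrades gracefully to plain PLS1 — the test suite checks exact
agreement with an independently coded NIPALS PLS1 in that case. The
sign convention orients `t_pred` positively with the MetS class.
Projection of new samples applies the stored preprocessing, removes
the stored orthogonal variation, and scores on `w`; projecting the
training data reproduces the training scores to machine precision.

Variable influence is the signed predictive loading: magnitude ranks
the contribution, sign says elevated versus depleted in MetS.

## Thresholding and calibration

The decision threshold is the Youden maximizer of
sensitivity + specificity − 1, swept over the midpoints between
consecutive distinct scores plus sentinels beyond both extremes; a
sample is called positive when its score exceeds the threshold.
Midpoints avoid ambiguity at data points; ties (including
floating-point ties, tolerance 1e-12) break toward the smallest
threshold.

MetSCORE is a logistic calibration of `t_pred`: a weighted logistic
regression of the label on `t_pred` with class weights inversely
proportional to class frequency (both classes carry equal total
weight, countering the ~2% prevalence), slope required positive, and
the intercept then *replaced* by `−slope × threshold`. The replacement
makes `MetSCORE(threshold) = 0.5` an exact identity rather than an
approximation, at the cost of discarding the fitted intercept — the
score is a monotone re-expression of `t_pred` anchored at the decision
threshold, not a maximum-likelihood class probability. Under complete
separation the weighted fit does not converge and the slope grows
large; the warning is suppressed deliberately because only the slope's
sign and scale are consumed and the resulting score remains strictly
increasing and bounded in (0, 1). (In double precision the sigmoid
saturates for |linear predictor| ≳ 37; strict monotonicity is asserted
within the representable range.)

## Validation design

* **Split**: unstratified random 80/20, seeded.
* **AUROC**: rank-based (ties one half), DeLong 95% interval.
* **Repeated CV with permutation**: stratified k-fold (the rare class
  would otherwise vanish from folds at realistic prevalence), the full
  selection + fit re-run inside every training fold — variable
  selection never sees a fold's test samples. A dedicated test
  demonstrates why: selecting on the full data and then
  cross-validating inflates AUROC on null data, and the pipeline
  exposes that leaky path only as an explicitly labelled diagnostic
  (`cv_with_fixed_variables()`). Each permutation replicate shuffles
  the profile vector across samples once (breaking every
  variable–profile association while preserving prevalences), then
  runs one round of stratified k-fold CV; the p-value uses the
  add-one estimator `(1 + #{perm ≥ obs}) / (n_perm + 1)`, whose floor
  is 1/(n_perm + 1).
* **Per-factor evaluation**: AUROC of the score against each risk
  factor separately (decoded from the profiles); constant factors are
  skipped with a warning.

## Urine spectra and binning

Spectra are (ppm, intensity) grids. The analysed region is
[0.5, 9.5] ppm minus the water window (4.7, 5.0); normalization
divides by the total intensity of that region (the water window is
discarded from analysis, so it is excluded from the total — whether
normalization precedes or follows the exclusion is ambiguous in
general practice; this package's choice is stated here, not claimed
universal). Binning tiles the region with 290 half-open 0.03-ppm bins
(140 + 150 per segment, final bin closed), each named by its centre.
The two segments' edge vectors are shared between the bin table, the
binning loop and the retained-region mask, so Σ bins = Σ retained
intensities holds exactly in floating point, and shuffling or
reversing the grid leaves the bin table unchanged. Bin centres derive
from the segment starts (0.515, 0.545, … and 5.015, 5.045, …);
registering centres at exact multiples of 0.03 ppm cannot tile the
stated segments with 140 + 150 bins without one bin straddling the
5.0 ppm water edge, so the segment-start registration is used.

The spectrum simulator is a sum of Gaussian peaks plus white noise
clipped at zero — sufficient for the binning arithmetic, and
deliberately not a lineshape model: no J-coupling, no baseline roll,
no peak-position drift, no phasing artifacts.

## The synthetic cohort generator

The generator defines the package's reference study conditions; it is
a data-generating stand-in for a cohort that is not publicly
redistributable, and its defaults were chosen once:

* **Prevalences**: the 16 profile probabilities of a large
  working-population serum cohort (asymptomatic 68.5%, WHO-MetS
  ≈ 2.0%); gender 37.5% female, independent of profile; ages from a
  normal(45, 11) truncated to 18–81 years.
* **Correlation structure**: each variable belongs to exactly one
  block; members share a latent Gaussian factor giving equicorrelation
  ρ (0.9 for the seven lipoprotein clusters — VLDL/IDL, LDL 4–5,
  LDL 1–3, LDL 6, HDL 1–3 with and without triglycerides, HDL 4; 0.7
  for derived lipid ratios, which share components with the
  primaries; 0.6 amino acids; 0.7 ketone bodies; metabolite
  singletons otherwise). Equicorrelation is the simplest structure
  that makes the clustering stage's job well-posed.
* **Effects**: additive over active risk factors, in SD units —
  dyslipidemia raises VLDL/IDL (+1.0), dense LDL (+1.0), TG-rich HDL
  (+0.9) and LDL 6 (+0.8) while depleting non-TG HDL (−0.9) and light
  LDL (−0.6); diabetes is dominated by glucose (+1.5), ketones (+1.0)
  and lactate; obesity and hypertension act through amino acids
  (proline, phenylalanine) and VLDL. The magnitudes are a free choice
  (no generative description of the real cohort exists beyond
  prevalence tables and effect directions); they were set to the
  0.5–1.5 SD range typical of published profile-contrast heatmaps and
  not revisited.
* **Covariates**: small gender shifts (HDL higher in females,
  creatinine lower) and age slopes (VLDL/LDL rising ~0.01 SD/year).
* **Scale**: values are `baseline + SD-unit Gaussian` with baselines
  10 (metabolites) / 100 (lipoproteins), keeping concentrations
  positive for the log transform while leaving all SD-unit statements
  exact on the raw scale.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: non-Gaussian tails and skewness of real
concentrations, prevalence–age confounding, batch and sub-cohort
effects, medication effects, missing values, and the full
cross-correlation network between metabolite and lipoprotein blocks
(only block-diagonal plus effect-induced correlation is simulated).
Results on the generator demonstrate the pipeline's correctness and
calibration contracts, not clinical performance.

## Numerical choices and problem sizes

* Sample SD (n − 1) everywhere; seeded RNG isolated with a
  save/restore wrapper so package functions never disturb the
  caller's stream; one global seed fans out to per-stage seeds by a
  fixed affine map (kept below 2³¹).
* Youden tie tolerance 1e-12; orthogonal-weight degeneracy threshold
  1e-8; bin-edge handling shares exact edge vectors (above).
* The SOM is batch-trained: BMU assignment by Euclidean distance,
  codebooks replaced by Gaussian-neighborhood-weighted means, radius
  decaying linearly (default from a third of the grid diagonal to
  0.3) over 20 epochs; initial codebooks are a seeded sample of data
  rows; empty neighborhoods keep their codebook. With a fixed,
  vanishing radius the update is exactly the Lloyd step, so the
  quantization error is non-increasing — that is the monotonicity
  property the tests assert. Grid size defaults to the ⌈5√n⌉-cells
  heuristic in near-square shape; cells are grouped by Ward.D2 on the
  codebooks, cut at k = 6. The map inputs are the model's selected
  variables under the model's own log/autoscale preprocessing.
* Reference problem sizes: the workflow and acceptance computations
  run on n = 2000 cohorts with 153 serum variables; cross-validation
  reports use 2 repetitions × 5 stratified folds with up to 100
  permutations; Monte-Carlo structure checks use n = 5000–20000.
  These sizes were chosen so every property being checked (effect
  recovery at ±3 SE, exact block recovery, the 1/101 permutation
  floor) is statistically resolvable.

## Limitations

* The MetSCORE is anchored to the WHO definition through its training
  label; scores under other definitions require registering the
  definition and refitting.
* The calibration is a monotone anchor, not a calibrated posterior
  probability; do not read MetSCORE as P(MetS | data) for a new
  population with a different prevalence.
* One orthogonal component is fixed; panels with several strong
  class-independent factors (e.g. heavy batch structure) would leave
  residual orthogonal variation in `t_pred`.
* The SOM training schedule is a reasonable default, not an optimized
  one; map geometry is for exploration, and no prediction is done
  from the map.
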