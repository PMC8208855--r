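---
title: "The M3 multimodal multiclassifier: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The M3 multimodal multiclassifier: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
what is computed, under which conventions, which parameters matter, and
where a genuinely open design question was decided one way rather than
another.

## 1. The problem and the model

The goal is two-group discrimination (schizophrenia patients, SZ, versus
healthy controls, HC) from five modality-specific feature blocks per
subject: four resting-state fMRI metrics — ALFF, ReHo, degree centrality,
voxel-mirrored homotopic connectivity — and structural grey-matter density,
each summarized as one mean value per atlas region. With a 246-region
parcellation this gives 1230 features per subject, far more than the
typical cohort size, which drives every modelling choice below.

Rather than concatenating all modalities into one long vector, the M3
scheme trains one linear discriminant per modality and fuses the five base
classifiers by weighted voting. The base classifier is
**maximum-uncertainty LDA** (MLDA): the pooled within-class scatter

$$S_w = \sum_{c \in \{0,1\}} \sum_{i \in c} (x_i - \mu_c)(x_i - \mu_c)^\top$$

is eigendecomposed, every eigenvalue below the eigenvalue mean
$\bar\lambda$ is replaced by $\bar\lambda$, and the discriminant is
$w = S_*^{-1}(\mu_1 - \mu_0)$ with the decision boundary at the midpoint of
the projected class means. The eigenvalue floor makes $S_*$ positive
definite whenever $\bar\lambda > 0$, so the fit exists even with more
features than subjects — the regime the selection step can still produce at
lenient thresholds. The underlying assumption is that directions of very
small within-class scatter are dominated by estimation noise ("maximum
uncertainty") and should not be trusted with large discriminant loadings.

Fusion: each base classifier votes $\hat y_m \in \{-1, +1\}$, the vote
score is $s = \sum_m w_m \hat y_m \in [-1, 1]$, and the predicted label is
SZ when $s > 0$. The continuous score $s$ is what the ROC/AUC is computed
from.

## 2. Evaluation protocol

All supervised steps — standardization, t-test selection, MLDA fits, voting
weights — are functions of the training rows of each leave-one-out fold
only; the held-out subject is transformed with training parameters and
scored. The selection P threshold is grid-searched over the 50-point ladder
0.001–0.050 (step 0.001) by maximizing LOOCV accuracy; ties break toward
the smallest threshold (fewest features, deterministic). The threshold is
selected on the same LOOCV whose performance is reported — this reproduces
the protocol of the line of work the package implements and is knowingly
optimistic; a nested protocol can be emulated by running
`m3_grid_search()` inside an outer loop, and the permutation test (which
reapplies the entire procedure to label-shuffled cohorts) is the honest
significance control for the protocol as a whole.

Significance machinery:

* **Accuracy permutation test** — the group labels are shuffled (a
  permutation of the label multiset), the whole pipeline is rerun, and the
  p-value is the fraction of permutations reaching the observed accuracy.
  The plain `count / n_perm` estimator is the default and can return 0; a
  `(count+1)/(n_perm+1)` variant is available (`add_one = TRUE`). "Reaching"
  is implemented inclusively (`>=`), the conservative reading.
* **AUC permutation test** — permutes the vote scores against fixed labels.
* **DeLong test** — compares two correlated AUCs on the same subjects via
  placement-value covariance. Identical or rank-equivalent score vectors
  give zero variance of the difference; by convention `z = 0, p = 1`.

## 3. Parameters that matter

| Parameter | Default | Units | Rationale |
| --- | --- | --- | --- |
| band-pass | 0.01–0.10 | Hz | standard low-frequency BOLD band; ALFF integrates this band of the unfiltered spectrum |
| DC threshold | r > 0.25 | — | conventional suprathreshold-connection cut; strictly one-sided (anticorrelations never count) |
| ReHo neighbourhood | 27 | voxels | full 3×3×3 cluster; 7 and 19 available |
| smoothing FWHM | caller-set (4 mm functional, 8 mm structural typical) | mm | applied after metric computation/standardization |
| P-threshold grid | 0.001–0.050 step 0.001 | — | 50 candidates; searched, not assumed |
| voting weights | training accuracy, normalized | — | see §5 |
| permutations | 1000 (tests use 200) | — | resolution of the permutation p |

## 4. The synthetic-data generator

`sim_cohort_features()` draws each modality block from a multivariate
normal with exchangeable within-block correlation (default 0.3), unit
marginal variance scaled by `noise_sd`, and injects each planted effect as
a mean shift of `d` pooled standard deviations on the patient group — so
Cohen's d is the single effect parameter and is recoverable from the table.
The default cohort is 45 patients / 64 controls over 246 regions × 5
modalities, matching the cohort scale the pipeline is meant for.
`sim_timeseries_image()` builds small 4D volumes whose atlas regions carry
known sinusoidal spectral content, mirror-symmetric when requested, with a
toy atlas and random-walk motion parameters; `sim_demographics()`
moment-matches group ages exactly (affine rescale) so summary-statistic
tests on the output are deterministic.

What the generator deliberately does **not** emulate: hemodynamic response
shapes, physiological noise spectra, scanner drift/artefacts, spatial
autocorrelation between regions, site effects, or realistic per-modality
effect topographies (no reference values exist for those). Passing tests
therefore demonstrate correctness of the *procedure* — selection inside
folds, fusion arithmetic, calibration of the permutation machinery — not
expected performance on real cohorts.

Test and acceptance runs use cohorts of 109 subjects (45/64) at 1230
features for the full grid search, 40 subjects at 100 features inside
permutation-calibration loops, and 20-seed repetitions for recovery
properties — sizes chosen to exercise the full pipeline while keeping a
complete run in minutes on a single CPU.

## 5. Decisions where the design was genuinely open

* **"Fisher-Z transformation" per metric.** Only VMHC is
  correlation-valued, so `atanh` is applied there (|r| clamped at
  1 − 10⁻⁷). For ALFF/ReHo/DC the "z map" reading — in-mask mean/SD
  z-standardization — is used, since `atanh` is undefined for Kendall's W
  and unbounded amplitudes. `standardize_map()` exposes both conventions
  explicitly.
* **Voting weights.** The weighting rule of "weighted voting" is not
  uniquely determined by the name; this package uses each base classifier's
  training-set accuracy normalized to sum 1 (the convention of the method
  family it implements), with `weight_rule = "uniform"` as the alternative.
  An abstaining modality (empty selection) gets weight 0 and the rest are
  renormalized.
* **Standardization of the test subject.** Test rows are transformed with
  training parameters (no leakage). A literal "normalize the test set
  separately" is statistically ill-defined for a single held-out subject
  (its own SD does not exist), so the leakage-free reading is the only one
  implemented.
* **Scatter, not covariance.** $S_w$ is the *sum* of class-centered outer
  products. Flooring eigenvalues of $S_w$ or of $S_w/n$ is equivalent for
  the decision rule (the floor is scale-covariant); the sum is fixed for
  bit-reproducibility.
* **Tie rules.** A discriminant score of exactly 0, or a vote score of
  exactly 0, classifies as HC. A flat accuracy curve returns the smallest
  threshold.
* **Untrainable folds.** `m3()` refuses a training set on which all five
  selections are empty. Inside LOOCV and permutation loops such a fold is
  scored 0 (⇒ HC, the tie rule) and counted in `n_untrainable_folds`, so a
  rare all-abstain fold under permuted labels cannot abort an entire
  permutation run while still being visible in the result.
* **Selection boundary.** `P <= threshold`, equal-variance t, two-sided;
  features with zero training variance are dropped before selection.

## 6. Numerical choices

* Band-pass filtering is an ideal rectangular mask on the discrete Fourier
  transform (parameter-free, reproducible); ALFF is the mean single-sided
  amplitude spectrum over the band, computed on the unfiltered
  (nuisance-regressed) series.
* Nuisance regression solves least squares by QR; numerically constant
  covariate columns (e.g. the global signal of an already-GSR'd image) are
  dropped before the solve, and a genuinely rank-deficient design falls
  back to a pseudoinverse with a warning. This makes global-signal
  regression idempotent to numerical tolerance.
* Kendall's W uses the plain concordance formula over per-series midranks;
  voxels with fewer than two in-mask series score 0 and are counted.
* Gaussian smoothing is separable with σ = FWHM/(2√(2 ln 2)) per axis in
  voxel units, kernel renormalized at edges and around missing values, so
  constant maps are exact fixed points.
* The grid search computes each fold's standardization and t statistics
  once and caches MLDA fits on the selected-feature set, which only changes
  when the threshold crosses an observed P value — a pure speed
  optimization verified against the naive per-threshold rerun in the test
  suite.
* ROC AUC uses midranks (ties count ½), making
  `roc_auc(s) + roc_auc(-s) = 1` exact.

## 7. Known limitations

* Voxelwise *preprocessing* (slice timing, realignment, segmentation,
  spatial normalization) is out of scope; images enter this package already
  aligned, and GMD maps enter as ready 3D volumes.
* The mirror axis for VMHC is the first array axis; real data must be
  registered to a symmetric template upstream.
* The threshold is selected and evaluated on the same LOOCV (see §2);
  reported accuracies are optimistic in exactly the way the permutation
  test accounts for.
* Only volumetric label atlases are supported for feature extraction;
  surface parcellations and sphere-around-coordinate ROI construction are
  the user's responsibility.
* The plain `count / n_perm` permutation p can be exactly 0; use `add_one = TRUE` when
  a strictly positive estimate is required.
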