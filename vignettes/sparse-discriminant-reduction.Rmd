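---
title: "Sparse discriminant reduction, stability selection, and nested cross-validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse discriminant reduction, stability selection, and nested cross-validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pldacv)
```

## The model

The pipeline addresses two-class discrimination of masked 3-D scalar brain
volumes — smoothed gray-matter-volume maps or signed log-Jacobian deformation
maps — in the regime where the number of voxel features `p` vastly exceeds
the number of subjects `n`. Each subject's in-mask voxels are flattened (in a
fixed row-major order over voxel coordinates) into a row of an `n × p` matrix
`X`, with labels H (controls) and D (patients).

Fisher's discriminant seeks the direction maximizing between-class over
within-class variance. With two classes the between-class scatter is the
rank-1 outer product of the class-mean difference `d = m_H − m_D`, so
`vᵀ S_B v = (dᵀ v)²` and the full matrix is never needed. The within-class
scatter is replaced by its diagonal `s²_j` (pooled sum of squared deviations
from the class means, with no degrees-of-freedom normalization), which avoids
the singularity of the full scatter at `p ≫ n`. The sparse direction solves

$$\max_v \; (d^\top v)^2 - \lambda \sum_j s_j |v_j|
\quad \text{s.t.} \quad \sum_j s_j^2\, v_j^2 = 1 ,$$

where the penalty weights `s_j` make the problem — objective, constraint and
active set alike — exactly invariant under a global rescaling of the
features. `λ = 0` keeps every feature; increasing λ zeroes coefficients; at a
data-dependent `λ_max` (available as `plda_lambda_max()`) the direction
collapses to the zero vector.

### The MM solver

`plda_fit()` uses minorization-maximization. The quadratic `(dᵀv)²` is
minorized by its tangent at the current iterate; the constrained maximizer of
the tangent minus the penalty has the closed form

$$u_j = \operatorname{soft}\!\big(2 d_j (d^\top v),\; \lambda s_j\big)\big/ s_j^2,$$

renormalized to the constraint. This update never decreases the objective
(asserted at every iteration in the test suite). Numerical choices, all of
which are open in the underlying method:

* **Initialization** — the closed-form λ = 0 maximizer `v_j ∝ d_j / s²_j`.
  It is deterministic, and a fixed point when λ = 0.
* **Convergence** — relative objective change below `tol = 1e-6`, or collapse
  to the zero vector; `max_iter = 1000`. Non-convergence sets a flag instead
  of raising, so λ-grid sweeps always complete.
* **Tie at the threshold** — `|b_j| = λ s_j` exactly gives coefficient 0
  (the closed-form maximum of the soft-threshold at equality), a
  deterministic tie-break.
* **Sign** — `dᵀv ≥ 0`, so weight maps are comparable across subsamples and
  folds.
* **Constant features** (`s²_j = 0`) are dropped with a warning and receive
  weight 0; brain-masked real data should have none.

On instances with `p ≤ 3` the fitted objective agrees with an exhaustive
grid-with-zoom maximization over the constraint ellipsoid to 1e-4.

## Stability selection

Rather than tuning λ by cross-validated error (prone to sampling error at
these sample sizes), `run_stability()` fits the sparse direction on `K`
random subsamples and computes per-feature selection probabilities
`P_j(λ)`, the fraction of subsamples in which feature `j` had a nonzero
coefficient. The selected set is `{j : P_j ≥ threshold}`.

* **Subsampling scheme** — stratified half-samples without replacement
  (`⌊n_c/2⌋` per class), the convention of the stability-selection
  literature; the fraction is configurable.
* **K = 100** by default, the value used in the motivating study; the
  desk-scale demonstrations below use smaller K since their cohorts are an
  order of magnitude smaller.
* **Threshold 0.99, inclusive.** The boundary convention matters because
  probabilities are exact multiples of 1/K: a feature selected in 99 of 100
  subsamples has `P_j = 0.99` and *is* selected.
* A subsample on which the fit collapses to zero contributes all-zero
  indicators and is counted (`n_zero_collapses`). Features constant within a
  subsample are dropped for that subsample only.
* Per-subsample seeds are pre-drawn from the root seed, so the profile is
  reproducible bit-for-bit and independent of evaluation order (serial or
  parallel).

Alongside `P`, the profile accumulates each feature's mean nonzero
coefficient across the subsamples where it was active; averaged again over
nested-CV folds this yields the mean discriminative-weight maps.

## Baseline reductions

* `ttest_select()` — per-feature two-sided two-sample Student's *t* with
  pooled variance and `df = n − 2` (the equal-variance form, matching the
  named test; Welch would be defensible but is not what the name says),
  selecting raw `p < threshold`, or Benjamini–Hochberg-adjusted `p` under
  `correction = "fdr"` — BH being the standard neuroimaging FDR procedure.
  Selections nest across thresholds, and FDR is never more permissive than
  the same raw threshold.
* `pca_extract()` — unsupervised: center on the training mean, keep all right
  singular directions with nonzero singular value (at most `n_train − 1`),
  project train and test rows. Covariance (not correlation) PCA on centered,
  unscaled features, consistent with "all components with nonzero
  eigenvalues".
* `no_reduction()` — the identity selection.

## Classifiers

* `lda_train()` — equal-prior Gaussian discriminant with pooled covariance.
  At `p ≫ n` the pooled covariance is singular; the weight vector
  `w = S⁺(m_D − m_H)` is computed via the SVD of the within-class-centered
  training rows, i.e. the Moore–Penrose pseudo-inverse restricted to the
  ≤ (n−2)-dimensional subspace the data actually span — no `p × p` matrix is
  formed, and the rule reduces to classical LDA when the covariance is full
  rank (cross-checked against a dense pseudo-inverse oracle and `MASS::lda`
  in the tests). A diagonal-covariance variant is available
  (`diagonal = TRUE`) for sensitivity analysis.
* `svm_train()` — soft-margin linear SVM (libsvm via e1071), `C = 1`, no
  feature scaling and no inner tuning: the pipeline under study reports no
  tuning, and results do depend on C.
* Both classifiers share the sign rule *predict D iff `w·x + b > 0`*, with a
  decision value of exactly 0 assigned to H — a deterministic tie-break.
  Equal priors are used throughout (group sizes are equal in all the designs
  here); priors are configurable only through the class sizes themselves.

## The two cross-validation designs

`loocv_c()` fits the reduction **once on all n subjects** and cross-validates
only the classifier. For supervised reducers the test subject's label has
then influenced the feature set in every fold — the design under critique.
`loocv_rc()` nests the entire reduction (including all K stability
subsamples) inside each fold. Both return per-fold records, confusion counts,
a per-feature selection-count map (for design *c* it is `n ×` the selected
indicator), and the mean nonzero-weight map.

**Empty selections.** With an inclusive 0.99 threshold a fold can select
nothing (on null data this is the norm). Aborting an n-fold run for one
degenerate fold is worse than a flagged fallback, so by default the fold
falls back to the features attaining the maximum selection probability (for
the t-test reducer: the smallest-p feature), with a logged message;
`on_empty = "error"` restores strictness. The fallback preserves the leakage
being demonstrated: under design *c* even the fallback features are chosen
with knowledge of all labels.

**Metrics and tests.** Accuracy, sensitivity and specificity are pure
functions of the confusion counts, reported in percent; an empty class yields
`NA`, never a silent 0. `mcnemar_compare()` uses the exact two-sided binomial
form when discordant pairs ≤ 25 and the continuity-corrected χ² otherwise
(both forceable — the original report does not say which it used);
`binomial_vs_chance()` is one-sided (greater than 0.5), matching the
directional claim it supports.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of preprocessed
morphometry maps, not their physics:

1. per-voxel noise scales drawn once as `noise_sd · lognormal(0, σ_h)`
   (`variance_heterogeneity`, default 0.2) — heterogeneous variance across
   the brain;
2. per subject, white Gaussian noise scaled voxel-wise, then Gaussian
   smoothed (separable kernel, `σ = FWHM/2.3548`, default FWHM 3 voxels —
   emulating the 8-mm smoothing typical of volumetric pipelines at
   desk-scale voxel counts), then masked;
3. class-D rows shifted by the true effect vector: spherical clusters with
   amplitude `delta`, placed strictly inside the mask (a cluster crossing the
   mask is an error naming the cluster). The shift is applied after
   smoothing, so the planted effect size is exact in expectation and
   group-mean differences converge to `delta` at support voxels.

What it does **not** emulate: registration error, segmentation artifacts,
bias fields, anatomical covariance structure beyond local smoothness, site
or age effects. Passing tests therefore show the pipeline's statistical
properties (bias, calibration, recovery), not clinical performance on real
MRI.

Default desk-scale geometry: a 24³ grid with an ellipsoidal mask
(~3,900–4,600 in-mask voxels) and `n = 20 + 20`. Real-data scale
(`p ≈ 7.5×10⁵`) is supported by the same code paths — nothing materializes
more than `O(np)` — but is not exercised by the tests.

## Study conditions used in the demonstrations

* **Leakage-bias demonstration** (`bias_demo()`): 10 null cohorts,
  `n = 20 + 20`, `p = 2000` (10×20×10 box mask), LDA classifier, reducers
  t-test (`p < 0.01`), pLDA stability (`λ = 0.5`, `K = 20`, threshold 0.99),
  PCA, and none. λ = 0.5 sits in the operating range where half-sample fits
  retain roughly 60% of features and a handful of spuriously discriminative
  features reach the 0.99 threshold on the full data — the regime where
  non-nested selection leaks most visibly. K = 20 is the desk-scale choice
  for these 40-subject cohorts (the package default stays at 100). The
  chance band is the central 95% binomial interval; note that nested LOOCV
  on null data tends to sit slightly *below* 50% (the left-out subject's
  class is underrepresented in training — a known leave-one-out artifact),
  comfortably inside the band.
* **Strong-signal fixture:** one cluster of radius 2.5 voxels (81 voxels),
  `delta = 5 × noise_sd`, on the default ellipsoid geometry, `K = 50`,
  `λ = 200`. The λ was chosen the way operating grids are chosen in
  practice — by the feature counts they produce (here: half-sample fits
  reduced to roughly the support size) — and gives exact support recovery
  with zero off-support selections and 100% nested-LOOCV accuracy.

## Known limitations

* Two classes only; the diagonal within-class estimate is the only penalized
  variant offered.
* No inner tuning loops (λ, C): λ is swept transparently instead, mirroring
  the grid-plus-stability design the method was built around.
* The exact-vs-χ² McNemar switch at 25 discordant pairs is conventional, not
  canonical.
* The generator's defaults aim at testability (clear signal, modest size);
  no claim is made that they match the effect sizes of any real disorder.
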