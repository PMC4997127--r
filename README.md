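# pldacv

Sparse penalized discriminant reduction and nested cross-validation for
two-class brain-volume classification.

## The problem

Whole-brain structural MRI studies that try to separate patients from healthy
controls face an extreme *p ≫ n* regime: hundreds of thousands of voxel-wise
features (smoothed gray-matter volumes, or log-Jacobian local-deformation
maps) against on the order of a hundred subjects. The standard remedy is to
reduce the feature set before classification — by mass-univariate *t*-test
selection, by unsupervised PCA, or by a supervised multivariate method. This
package implements one such supervised method, **penalized linear discriminant
analysis (pLDA) with stability selection**, together with the baselines, two
linear classifiers, and — crucially — the two ways leave-one-out
cross-validation (LOOCV) can be wrapped around the pipeline:

* **LOOCV(c)** — the reduction is fit once on *all* subjects and only the
  classifier is cross-validated. Supervised reducers thereby see the test
  subjects' labels. This design is *wrong* and optimistically biased, even
  when the reduction itself resamples internally.
* **LOOCV(rc)** — the reduction (including all of its internal resampling) is
  refit inside every fold on the n − 1 training subjects. This nested design
  is unbiased.

Because real clinical MRI cohorts of this kind are not publicly available, the
package ships a synthetic cohort generator (smooth Gaussian volumes,
heterogeneous per-voxel variance, planted discriminative clusters with known
support) so the bias of the non-nested design can be demonstrated and tested
at desk scale.

## The method

For classes H (controls) and D (patients) with per-feature class means
`m_H`, `m_D`, difference `d = m_H − m_D`, and the diagonal of the
within-class scatter `s²_j` (sum of squared deviations from each class mean),
pLDA finds the sparse discriminant direction `v` solving

```
max_v  (dᵀv)² − λ Σ_j s_j |v_j|     subject to   Σ_j s²_j v_j² = 1
```

using the rank-1 identity `vᵀS_B v = (dᵀv)²`, so no p × p matrix is ever
formed. The problem is solved by minorization-maximization (MM): each
iteration linearizes `(dᵀv)²` at the current iterate and the constrained
maximizer of the minorant is a closed-form soft-threshold,
`u_j = soft(2 d_j (dᵀv), λ s_j) / s²_j`, renormalized to the constraint. At
λ = 0 all features contribute; above a data-dependent λ_max every coefficient
is zero.

**Stability selection** fits pLDA on K stratified half-samples (K = 100 by
default) and records each feature's selection probability
`P_j(λ) = (1/K) Σ_k 1{v_j ≠ 0 in subsample k}`; the features with
`P_j ≥ 0.99` form the reduced set. Reduced data are classified with LDA
(pseudo-inverse pooled covariance, safe for p ≫ n) or a linear SVM, and
performance is reported as accuracy / sensitivity / specificity with
McNemar's test between pipelines and a one-sample binomial test against
chance.

## Worked example

Plant one spherical cluster (effect size 5 × noise SD, 81 voxels) in an
ellipsoidal mask, recover it by stability selection, and cross-validate with
the nested design:

```r
library(pldacv)

geom <- ellipsoid_geometry()          # 24^3 grid, ~3,900 in-mask voxels
spec <- synthetic_spec(geom, n_per_class = c(20, 20),
                       clusters = list(list(center = c(12, 12, 12),
                                            radius = 2.5, delta = 5)),
                       seed = 11)
g <- generate_cohort(spec)
g$cohort
#> <cohort> 40 subjects (20 H, 20 D) x 3912 features

prof <- run_stability(g$cohort, lambda = 200, K = 50, seed = 4)
prof
#> <selection_profile> p = 3912, K = 50, lambda = 200; 81 features with P >= 0.99

run <- loocv_rc(g$cohort, reducer_plda(lambda = 200, K = 50),
                classifier_lda(), seed = 5)
run
#> <cv_run> LOOCV(rc): n = 40, accuracy 100.0%, sensitivity 100.0%, specificity 100.0%
binomial_vs_chance(run)$p_value
#> [1] 9.094947e-13
```

The 81 features passing the 0.99 threshold are exactly the planted cluster,
and the nested LOOCV classifies all 40 subjects correctly — far better than
chance by the one-sample binomial test.

The leakage bias itself is one call:

```r
bd <- bias_demo(seed = 1)   # 10 null cohorts, n = 20+20, p = 2000
plot_bias_demo(bd)
```

On data with *no* class signal, the non-nested design scores well above the
95% chance band for the supervised reducers (t-test, pLDA) while the nested
design stays at chance; PCA and no-reduction show no gap.

`tidy()` / `glance()` methods return tibbles for every result type;
`autoplot()` draws selection profiles and accuracy-versus-λ sweeps;
`write_map()` / `read_cohort()` exchange maps and cohorts as NIfTI + CSV.

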