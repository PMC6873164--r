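---
title: "Multi-modal connectivity networks: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal connectivity networks: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Predicting which patients with mild cognitive impairment (MCI) will convert
to Alzheimer's disease (AD) is a central problem in dementia research.
Individual voxel- or region-level features from structural MRI (gray-matter
volume) or FDG-PET (glucose metabolism) have limited discriminative power
for this task; region-to-region *relationships* — connectivity — carry
additional information, but conventional connectivity estimators need many
scans per subject or collapse each region to a single summary value.

`mmcnet` builds an *individual* multi-modal connectivity network for each
subject from a single pair of images, by borrowing strength from an
auxiliary cohort of AD patients and normal controls (NC), and evaluates
those networks as features for sMCI-vs-pMCI classification (stable vs
progressive MCI, defined by 3-year conversion status).

## The method

The pipeline has three stages.

**1. Bagged regional PCA on the auxiliary domain.** For each of T
bootstrap replicates (default T = 200), subjects are resampled with
replacement, stratified so that each replicate contains exactly n_AD
AD subjects and n_NC controls. Within a replicate, each brain region and
modality gets a voxel-space PCA: the bootstrap-sample mean and the top S
eigenvectors of the voxel covariance. The rationale for bagging is that
auxiliary cohorts are small relative to voxel counts, so single-sample
eigenvectors are noisy; an ensemble of T bases gives a more stable — and,
crucially, T-fold richer — representation.

**2. Projection and region-wise multi-task sparse regression.** A target
subject's region-k voxel vector is centered with each replicate's bootstrap
mean and projected on that replicate's eigenvectors, giving a T x K matrix
per modality and PC index i. Connectivity is then quantified by K
regressions per PC index: region k's projected T-vector is the response,
the other regions' T-vectors are the regressors (region k's own column is
fixed at zero), and the two modalities form two tasks coupled by the
l2,1 (group-lasso) penalty

> min over W of  1/2 * sum_m ||y^m − X^m w^m||^2 + lambda * sum_j ||W_j.||_2

so a regressor region is selected jointly for both modalities or not at
all. The penalty level is specified as a *ratio* of lambda_max, the
smallest value at which the solution is entirely zero, computed per
problem. The solver is accelerated proximal gradient (FISTA) with a
monotone safeguard; the group soft-threshold prox yields exact zero rows,
so supports are read off without any epsilon. Convergence is certified by
the KKT residual (default 1e-6): active rows must satisfy
grad_j = −lambda * W_j/||W_j||, inactive rows ||grad_j|| <= lambda. We
deliberately made the certificate, not an objective-stall heuristic, the
stopping rule — a stalled objective merely restarts the momentum — because
downstream support extraction depends on the solution being exact.

**3. Binary-to-decimal edge weights.** Across the S PC indices, each
(target k, regressor j) pair accumulates a length-S binary support
pattern. It is read as a binary number with PC 1 the most significant bit
and normalized by 2^S − 1, so edge weights lie on the grid
{0, 1, ..., 2^S − 1}/(2^S − 1) and supports on top-ranked PCs dominate.
The resulting K x K matrix is asymmetric (row k is "k as target") with a
structurally zero diagonal.

For diagnosis, the K(K−1) off-diagonal weights are vectorized per subject
and fed to the published evaluation protocol: leave-one-out
cross-validation where each fold's training half drives (i) a pooled-t
filter keeping the top 20% of edges by |t|, (ii) a nested stratified
5-fold search for the linear SVM cost C over 2^beta, beta in −8..8, and
(iii) SVM-RFE ranking with a step schedule of 500 removals above 10,000
surviving features, then 50, then 5 below 1,000, then 1 below 100. The
classifier is evaluated at feature fractions from 10% of the filtered set
in 5% steps; accuracy, sensitivity (pMCI positive), specificity and AUC
are aggregated per fraction.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `T_boot` | 200 | bootstrap replicates; also the sample size of each region-wise regression. Desk-scale runs in this package use 50. |
| `S` | grid 1..12 | PCs per region; also the bit-length of the edge encoding. Desk-scale runs use 5. |
| `lambda_ratio` | 6e-3 | penalty as a fraction of per-problem lambda_max. The published grid is {1..10} x 1e-3 at T = 200 and K = 246; at desk scale (T = 50, K = 30) those values produce fully dense networks, and our calibrated working value is 0.1. |
| `filter_keep_frac` | 0.20 | t-filter retention (20% of 60,270 edges is 12,054 at full scale). |
| `C_grid` | 2^(−8..8) | SVM cost candidates; ties resolve to the smallest. |

## What the synthetic generator emulates

`simulation_config()` plants three ingredients into two-modality regional
voxel data:

- **Group mean shifts.** AD subjects shift along a per-region, per-modality
  *effect map* by `effect_size` noise-SD units; sMCI and pMCI shift by
  attenuations a_sMCI = 0.2 and a_pMCI = 0.8 of the AD shift. Effect maps
  are zero-mean unit-norm voxel patterns: we model disease as sub-regional
  spatial redistribution, so plain regional means carry little group
  signal — which is exactly why a regional-mean baseline classifier is the
  right control for the network features.
- **Latent couplings.** Selected region pairs share a per-subject standard
  normal latent, expressed in both modalities through unit-norm coupling
  maps with loading 1.5. These are the connectivity ground truth.
- **Disease-modulated connectivity.** Each coupling is expressed at
  `loading * (1 − delta * a)` for a subject with disease score a (1 for
  AD, 0 for NC, the attenuations for MCI), default delta = 0.9.
  Connectivity weakening along the AD continuum — progressive
  disconnection — is the phenomenon that makes connectivity features
  diagnostic in the first place; without it, group membership enters the
  projected data only as replicate-constant offsets that standardization
  removes (and that are symmetric about the stratified auxiliary mean
  anyway), and *no* connectivity method could separate the MCI subtypes.
  We verified both regimes empirically: with delta = 0 the edge features
  test at chance; with delta = 0.9 the planted pairs dominate the
  edge-wise group statistics.

Calibration was done once and pinned: `noise_sd = 0.3`, `effect_size = 3`,
loadings 1.5. The guiding constraint is the Marchenko–Pastur bulk edge:
with p ≈ 30 voxels and n = 120 auxiliary subjects, the top noise
eigenvalue is about `noise_sd^2 * (1 + sqrt(p/n))^2`; planted directions
must carry variance above that edge or regional PCA cannot find them.

The generator does **not** emulate spatial autocorrelation, scanner and
site effects, partial-volume mixing at region borders, registration error,
or age/sex covariate structure. Passing tests therefore demonstrate that
the pipeline recovers the signal class it is designed for under honest
cross-validation — not that the published accuracy on real cohorts
transfers.

## Numerical choices

- Covariance eigenvectors come from the SVD of the centered data matrix;
  rank-deficient resamples are completed to S columns with a deterministic
  Gram–Schmidt basis (with a warning).
- PCA signs are arbitrary, so every bootstrap eigenvector is aligned to
  the full-sample reference eigenvector (non-negative dot product; exact
  ties force the largest-|loading| entry positive). Without alignment the
  replicate dimension of the projections would be sign-scrambled.
- Bootstrap resample indices are shared across regions and modalities
  within a replicate, so row t of every design matrix refers to the same
  resample — the regressions across regions would otherwise be
  meaningless.
- Design columns are z-scored over replicates and scaled to unit l2-norm;
  responses are centered. This makes the lambda-ratio convention and
  cross-column comparisons scale-free. Constant columns are zeroed with a
  guard. Both choices are exposed in code for sensitivity work.
- lambda_max excludes the target's own (zeroed) column, and the solver
  returns the exact zero matrix whenever lambda reaches the zero-solution
  threshold, avoiding one-ulp support leakage at the ratio-1 boundary.
- The t filter keeps `round(frac * p)` columns with half-up rounding
  (0.20 x 60,270 = 12,054 exactly).
- The RFE cost C is fixed to the nested-search winner found on the
  filtered set before elimination begins; the published protocol leaves
  the ordering open, and re-searching C inside every elimination step
  would multiply cost without a stated justification.
- The reported "peak" accuracy maximizes over the feature-fraction grid on
  the evaluation metric itself and is flagged optimistic, mirroring the
  published protocol; `honest_fraction = TRUE` selects the fraction inside
  each training fold instead.

## Desk-scale problem sizes

The bundled study runs at K = 30 regions, 20–40 voxels per region, groups
(60 AD, 60 NC, 40 sMCI, 40 pMCI), T = 50 replicates and S = 5 PCs; the
acceptance script and test suite use these sizes throughout. They are the
package's reference configuration for reproducible desk-scale analysis;
full-scale parameters (K = 246, T = 200, S = 12) are supported by the same
code paths.

## Known limitations

- Edge weights conflate "absent" and "weak" relationships: an all-zero
  support over S PCs encodes 0 regardless of why.
- The asymmetric network encodes region-to-region predictive relationships
  over the bootstrap ensemble, not communication or causality.
- Covariates (age, sex) are reported but not regressed out of the
  features.
- The desk-scale lambda working point (0.1) was calibrated on the frozen
  synthetic study; real cohorts at full scale should re-scan the published
  grid.
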