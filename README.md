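# mmcnet

Individual multi-modal brain connectivity networks from paired structural
MRI (gray-matter volume) and FDG-PET (glucose metabolism) regional voxel
data, for predicting conversion from mild cognitive impairment (MCI) to
Alzheimer's disease (AD).

## Who this is for

Neuroimaging researchers who have parcellated, spatially normalized
regional voxel values for two modalities per subject (or NIfTI volumes
plus an integer atlas) and want subject-level connectivity matrices —
rather than group-level covariance networks — as classification features
for stable-vs-progressive MCI (sMCI/pMCI).

## The method in brief

1. **Bagged regional PCA (auxiliary domain).** On an independent AD + NC
   cohort, draw T stratified bootstrap resamples (default T = 200); per
   resample, region and modality, keep the bootstrap mean and the top S
   voxel-space principal components.
2. **Projection.** Center and project a target subject's region-k voxels
   on each replicate's PCs, giving per modality and PC index i a T x K
   matrix X_PCi.
3. **Multi-task sparse regression.** For each target region k and PC
   index i, regress region k's T-vector on all other regions' vectors,
   with the two modalities as tasks coupled by an l2,1 penalty:

   min_W  ½ Σ_m ‖y^m − X^m w^m‖² + λ Σ_j ‖W_j·‖₂,   λ = ratio × λ_max

   Whole rows of W are zeroed exactly, selecting regions supported by
   *both* modalities jointly. An l1 single-task mode covers the
   single-modality lasso variant.
4. **Binary-to-decimal edge weights.** The S per-PC supports of pair
   (k, j) form a binary word (PC1 = most significant bit);
   Weight(k,j) = bin2dec(v) / (2^S − 1). The K x K network is asymmetric
   with zero diagonal.
5. **Evaluation.** Leave-one-out cross-validation with nested, leakage-free
   selection per fold: pooled-t filter (top 20% of edges), nested 5-fold
   search of the linear-SVM cost over 2^β (β ∈ −8..8), SVM-RFE with the
   500/50/5/1 step schedule, and a feature-fraction grid from 10% in 5%
   steps. Reports accuracy, sensitivity (pMCI positive), specificity, AUC.
   Edge-wise group differences use pooled two-sample t with
   Benjamini–Hochberg FDR (q < 0.05).

A synthetic-study generator (`simulation_config()` / `generate_study()`)
plants group mean shifts, cross-regional latent couplings shared by both
modalities, and disease-modulated coupling strength, so the entire
pipeline is testable without clinical data.

## Worked example

```r
library(mmcnet)

study <- generate_study(simulation_config())      # K=30, 60/60 AD/NC, 40/40 sMCI/pMCI
basis <- fit_bagged_basis(study$aux, projection_config(T_boot = 50, S = 5, seed = 11))
nets  <- build_cohort_networks(study$target, basis,
                               solver_config(lambda_ratio = 0.1), S = 5)
nets[[1]]
#> mmc_network: 30 regions, S = 5, 100.0% nonzero edges

feats  <- vectorize_networks(nets, study$target$metadata$group)
report <- loocv_classify(feats, selection_config(seed = 5))
report
#> cv_report: peak accuracy 90.00% at fraction 0.80 (sens 92.50%, spec 87.50%, AUC 0.9263)
#>   note: the peak point is selected on the evaluation metric (optimistic)

baseline <- loocv_classify(regional_mean_features(study$target),
                           selection_config(seed = 5))
baseline
#> cv_report: peak accuracy 62.50% at fraction 0.90 (sens 67.50%, spec 57.50%, AUC 0.6444)
```

The connectivity features recover the planted couplings (all 6 coupled
region pairs rank above the 90th percentile of their rows' edge weights)
and beat the regional-mean baseline by 27.5 accuracy points on the frozen
default study: the class signal lives in the planted coupling structure,
which regional means cannot see.

Cohort-level summaries follow the published conventions:

```r
chi_square_2x2(matrix(c(50, 25, 32, 19), 2, byrow = TRUE))
#> $statistic 0.2054...  $p 0.6504...
two_sample_t_summary(76.22, 6.28, 75, 74.95, 7.29, 51)$df
#> [1] 124
```

A thin CLI wraps the same functions
(`inst/cli/mmcnet simulate|train-basis|build-network|classify|groupdiff|run-all`),
and `run_pipeline()` replays a whole study from one YAML config and a
single seed.

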