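# r2sn — regional radiomics similarity networks and cross-modal coupling

`r2sn` quantifies how tightly a person's structural brain organisation is
coupled to their amyloid burden. From a pair of spatially aligned,
parcellated 3D volumes per subject — a T1-weighted structural image and an
amyloid-PET image — it builds one *regional radiomics similarity network*
(R2SN) per modality and measures the agreement between the two networks.
The package is aimed at neuroimaging researchers studying Alzheimer's
disease progression: the coupling score discriminates cognitively normal
from MCI and AD groups, tracks cognition and CSF biomarkers, and predicts
conversion from mild cognitive impairment to AD.

## The method

For each of the 246 regions of a Brainnetome-style parcellation, 47
radiomics features are extracted (14 first-order intensity statistics, 8
shape descriptors, 13 GLCM and 12 GLRLM texture features), min-max
normalized across regions within subject and modality, and pruned of
redundant features (greedy removal until no pair has |R| > 0.9). The R2SN
edge between regions *i* and *j* is the Pearson correlation of their
retained feature vectors, giving a symmetric 246 × 246 network per
modality.

Coupling between a subject's two networks:

- **Global coupling** = Corr(M, N), the Pearson correlation between the
  row-major upper-triangle edge vectors (length 246·245/2 = 30 135) of the
  structural network M and the amyloid network N.
- **Local coupling** of region *i* = Corr(M\[i, −i\], N\[i, −i\]), the
  correlation between that region's 245 off-diagonal connections in the
  two networks.

Downstream statistics mirror the standard analysis battery: ANOVA and
pairwise pooled t tests on age/sex-residualized scores, region-wise
contrasts Bonferroni-controlled at 0.05/246, partial Pearson correlations
with nine clinical measures at 0.05/9, CSF biomarker subgrouping
(Aβ+ iff CSF Aβ < 980 pg/ml, Tau+ iff CSF Tau > 245 pg/ml), and
Kaplan–Meier conversion analysis of MCI subjects stratified by coupling
quartiles with pairwise log-rank tests.

Because real multimodal cohorts cannot be redistributed, the package ships
a synthetic cohort generator with known ground-truth coupling, at two
levels of realism: edge-level network simulation (exact coupling control,
fast, used for statistical studies) and full voxel rendering through the
entire radiomics pipeline.

## Worked example

```r
library(r2sn)

v <- generate_paired_volumes(n_regions = 30, volume_shape = c(32, 32, 32),
                             target_coupling = 0.7, seed = 1, region_size = 64)
f_t1  <- minmax_normalize(extract_region_features(v$vol_a, v$parcellation,
                                                  subject_id = "sub-0001",
                                                  modality = "T1"))
f_pet <- minmax_normalize(extract_region_features(v$vol_b, v$parcellation,
                                                  subject_id = "sub-0001",
                                                  modality = "PET"))
pruned <- prune_redundant_features(list(f_t1, f_pet), threshold = 0.9)
length(pruned$retained)
#> [1] 21

net_t1  <- build_r2sn(pruned$matrices[[1]])
net_pet <- build_r2sn(pruned$matrices[[2]])
net_t1
#> R2SN: 30 regions (sub-0001, T1); edge range [-0.647, 0.856]

coupling_profile(net_t1, net_pet)
#> Coupling profile sub-0001: global = 0.7227; local range [0.3735, 0.9099] (30 regions)
```

Of the 47 registry features, 21 survive redundancy pruning on this small
synthetic pair; the measured global coupling (0.723) recovers the
generator's target (0.7) through the full voxel pipeline. Whole-cohort
runs go through `generate_cohort()` + `write_cohort()` + `run_pipeline()`
(or the CLI in `inst/cli/r2sn.R`), which write the coupling table, group
contrasts, clinical correlations, KM curves and a QC/manifest pair to the
output directory.

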