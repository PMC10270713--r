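---
title: "Cross-modal network coupling with r2sn: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal network coupling with r2sn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A regional radiomics similarity network (R2SN) represents one subject's
one-modality image as a graph: nodes are atlas regions, and the edge
between regions $i$ and $j$ is the Pearson correlation between the
regions' radiomics feature vectors. With features extracted from both a
structural T1 image and an amyloid-PET image of the same subject, two
networks $M$ (structural) and $N$ (amyloid) share one node set, and their
agreement is summarised by

$$\mathrm{GlobalCoupling} = \mathrm{Corr}\big(\mathrm{vec}(M),
\mathrm{vec}(N)\big),$$

where $\mathrm{vec}(\cdot)$ stacks the strictly-upper-triangular edges in
row-major order ($n(n-1)/2 = 30\,135$ values for $n = 246$ regions), and
per region by

$$\mathrm{LocalCoupling}_i = \mathrm{Corr}\big(M[i, -i], N[i, -i]\big),$$

the correlation of region $i$'s 245 off-diagonal connection weights
across modalities. The self-connection is fixed at 1 in both networks and
is excluded from the local score: a constant pair carries no information
and would only dilute the correlation. Both scores are stored raw (no
Fisher-z transform); none of the downstream statistics require one.

The premise, in Alzheimer's research terms: grey-matter organisation and
amyloid deposition are spatially structured in related ways in health,
and this structure-to-pathology correspondence degrades with disease, so
the coupling score should fall from cognitively normal (NC) through mild
cognitive impairment (MCI) to AD, track cognitive and CSF measures, and
stratify MCI conversion risk.

## Feature extraction

The default registry holds 47 features per region: 14 first-order
intensity statistics, 8 shape descriptors, 13 grey-level co-occurrence
(GLCM) features and 12 grey-level run-length (GLRLM) features, following
the classical radiomics catalogues. Conventions, where the field admits
several:

- **Quantization.** Texture features use 32 fixed-width bins spanning the
  region's own min–max. A constant region maps to a single bin, which
  yields zero entropy and zero GLCM contrast, as it should.
- **Direction pooling.** Co-occurrence counts (symmetric, distance 1) and
  run counts are accumulated over the 13 unique 3D directions before the
  scalar features are computed, so each feature is one direction-pooled
  value rather than an average of per-direction values. The GLRLM run
  percentage is normalised by voxels × directions accordingly.
- **Degenerate cells.** For a single-bin GLCM the correlation feature is
  defined as 1 (the joint distribution is perfectly predictable); a
  region too small to contain any voxel pair contributes a point-mass
  matrix.
- **Shape.** Surface area uses the exposed-voxel-face approximation, so a
  cube of side $s$ measures exactly $6s^2$; sphericity, compactness and
  spherical disproportion derive from that area, and the maximum 3D
  diameter is computed over surface voxel centres.
- **Variance flavours.** `fo_sd`/`fo_variance` are sample ($n-1$)
  statistics; skewness and kurtosis use population central moments, with
  kurtosis non-excess.

Features are min-max normalized *within subject and modality, across
regions* — each feature column is mapped onto $[0,1]$ — never across
subjects. Normalization of an already-normalized matrix is the identity.
A constant column is an error rather than a silent 0/0.

## Redundancy pruning

Highly collinear features would let a few feature families dominate every
edge. Pruning computes the feature × feature correlation over region rows
pooled across a designated reference set of matrices and greedily drops
the feature with the most $|R| > 0.9$ partners until no pair exceeds the
threshold; ties drop the feature latest in registry order, so of two
exact duplicates the later one goes. The threshold applies to $|R|$
because an anti-correlated duplicate is exactly as redundant as a
correlated one. The retained set is frozen and re-applied to new subjects
(`apply_feature_subset()`), guaranteeing a single shared feature space;
it is deliberately *not* recomputed per subject.

## Inferential layer

"Test with covariates" is implemented as residualize-then-test: scores
are replaced by OLS residuals on an intercept, age and a sex indicator
(complete cases only, listwise per analysis), and the plain ANOVA or
pooled-variance two-sample t runs on the residuals. For the two-group
case this is numerically near-identical to the group coefficient of an
ANCOVA; the residualization formulation was chosen because the analysis
battery names plain ANOVA/t tests with covariates. Partial correlations
residualize both sides on the covariates and use $n - 2 - k$ degrees of
freedom.

Multiplicity control is Bonferroni throughout: $0.05/246$ for region-wise
contrasts and $0.05/9$ for the nine-measure clinical battery. Biomarker
positivity uses strict inequalities — Aβ+ iff CSF Aβ $< 980$ pg/ml, Tau+
iff CSF Tau $> 245$ pg/ml — so boundary values classify negative, and
missing CSF propagates to an unknown status excluded from subgroup
contrasts.

For survival, MCI subjects are stratified at the empirical median or
quartiles of their global coupling (type-7 quantiles; ties at a cut go to
the lower stratum; S1 is the *lowest*-coupling quartile). Curves are
Kaplan–Meier product-limit estimates and comparisons are 1-df pairwise
log-rank tests, reported uncorrected, matching the convention of
reporting all six quartile p-values.

## The synthetic generator

Real paired T1/amyloid cohorts cannot be shipped, so every stage is
testable against generated data with known ground truth. Defaults are the
study conditions: groups of 248 NC / 390 MCI / 152 AD; group mean global
couplings 0.72 / 0.71 / 0.68 with subject SD 0.04; age
$\sim N(73, 7^2)$ truncated to [55, 95]; nine clinical measures linear in
coupling with signs MMSE/AVLT/FDG/CSF-Aβ positive and ADAS/Tau/p-Tau
negative, with noise SDs set so cohort-scale partial correlations land in
the $|R| = 0.2$–$0.4$ band; biomarker statuses derived from the simulated
CSF values through the same thresholds the analysis uses; exponential
MCI-to-AD conversion times with log-hazard decreasing in coupling,
administratively censored at a 96-month horizon (plus random early
censoring for a configurable fraction).

Two rendering levels:

- **Network level** draws each subject's two edge vectors from a
  correlated bivariate Gaussian (scaled to $[-1, 1]$; clipping sits ~4 SD
  out), so measured coupling equals the subject's target up to
  $O(1/\sqrt{m})$ with $m = 30\,135$ edges — about $\pm 0.003$. This is
  the workhorse for statistical simulations and covers the full
  $[-1, 1]$ target range.
- **Voxel level** draws a latent region × channel matrix controlling each
  region's mean intensity, spread and texture smoothness, renders
  modality A from it, and renders modality B from the mixture
  $\alpha L + \sqrt{1-\alpha^2} L'$ with the same mixture applied to the
  voxel noise field. At a target of 1 modality B is bit-identical to A,
  so the pipeline returns exactly 1. The map from target coupling to
  $\alpha$ is nonlinear because the feature pipeline is; it was
  calibrated once on a pilot grid (13 $\alpha$ values × 10 seeds, 60
  regions of ~125 voxels) and frozen as a monotone interpolation table.

The voxel path has a *coupling floor* of about 0.27: shape features are
computed from the region masks, and both modalities share one
parcellation, so even independently rendered intensities produce
partially matching networks. This mirrors real acquisitions, where both
modality networks are built on one atlas. Targets below the floor clamp
to the floor, so monotonicity of measured coupling in the target holds
strictly only inside the attainable range; property tests use a grid
within it.

The hazard slope default (25 per unit coupling) was calibrated once
against the prescribed operating characteristics of the quartile
analysis — stochastically ordered KM curves and extreme-quartile log-rank
separation at $n = 390$ MCI in at least 90% of replicates — and frozen.
A consequence worth knowing: the generator separates *adjacent* quartiles
more uniformly than the motivating study, whose two lowest-coupling
quartiles were statistically indistinguishable. Passing the ordering
tests therefore demonstrates correct machinery, not that real cohorts
order their quartile curves this reliably.

What the generator does not emulate: neuroanatomy, scanner physics,
partial-volume effects, spatial disease topography (group differences
act on the coupling scalar, not on specific regions), site effects, or
missing-data patterns of real cohorts. Tests passing on synthetic
cohorts validate the estimators and their calibration, not claims about
any particular dataset.

## Numerical and design notes

- Parcellations are jittered box lattices: parcels live on a cubic cell
  grid (cell side at least 4) with per-axis extents between 3 voxels and
  the cell side, so shape features vary across regions; every parcel has
  at least 27 voxels, keeping texture features computable.
- The edge-vector length for 246 regions is $246 \cdot 245/2 = 30\,135$
  by the combinatorial identity (an often-quoted figure of 30 315 does
  not match the arithmetic).
- A small group-mean arithmetic fact shapes expectations at small $n$:
  with means 0.72/0.71/0.68 and SD 0.04, the MCI–NC difference is a
  quarter of a subject SD, so at 60 subjects per group the sample means
  order correctly only ~91% of the time, and at full cohort scale the
  MCI-vs-NC t test has two-sided power ~0.86 at $\alpha = 0.05$. The
  test suite asserts rates these conditions can actually attain.
- Everything is deterministic given seeds: cohorts are bit-reproducible,
  pipeline re-runs reproduce identical CSVs, and the suite's simulation
  sizes (e.g. 100 recovery replicates at $n = 60$/group, 200 calibration
  replicates, 50 survival replicates at $n = 390$, a 12-subject voxel
  cohort on a $64^3$ grid with 60 regions) were chosen to keep the whole
  suite comfortably fast on a laptop while leaving Monte-Carlo margins of
  several SD on every rate assertion.

## Known limitations

- The 47-feature registry follows the classical catalogues'
  family structure; filtered (wavelet/LoG) feature classes are out of
  scope.
- Edges are kept signed and dense; graph sparsification and
  graph-theoretic summaries are out of scope.
- No spatial structure in group effects means region-level *recovery*
  (which regions decouple) can only be tested with synthetic planted
  effects at the statistics layer, not end-to-end through voxels.
- The survival generator uses an exponential baseline; real conversion
  hazards are not constant in time.
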