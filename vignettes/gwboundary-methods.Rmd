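---
title: "Methods: gray-white matter boundary Z-score and tissue volume mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gray-white matter boundary Z-score and tissue volume mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

T1-weighted MRI shows white matter (WM) brighter than gray matter (GM).
The cortical gray-white interface is therefore a band of intermediate
intensities whose width and sharpness reflect the local tissue transition.
In neurodegeneration this transition blurs: GM and WM signals converge near
the interface. `gwboundary` operationalizes this in three steps, all in a
common template space (inputs are assumed co-registered; the package does
no registration).

**1. Per-subject threshold band.** From the subject's partial-volume maps,
two intensity pools are formed: voxels with more than 50% GM
(`f_GM > 0.5`) and voxels with more than 50% WM. With pool means and
2-standard-deviation dispersions, the band is

$$\text{lower} = \mu_{GM} + \tfrac{1}{2}\,(2\sigma_{GM}), \qquad
  \text{upper} = \mu_{WM} - \tfrac{1}{2}\,(2\sigma_{WM}),$$

i.e. one sample SD above the GM pool mean and one below the WM pool mean.
Intensities between them are "too bright for typical GM, too dark for
typical WM" — the transition zone. The band narrows as the GM-WM contrast
collapses, which is exactly the disease signal: the algebraic width is
$(\mu_{WM} - \mu_{GM}) - (\sigma_{GM} + \sigma_{WM})$, and the first term
shrinks proportionally with contrast.

**2. Binary boundary map (gwBB) and boundary tissue volume (gwBTV).**
Voxels inside the band *and* carrying predominantly GM/WM tissue
(`f_GM + f_WM > 0.5`) get 1, the rest 0. The eligibility rule keeps CSF and
background voxels with coincidentally band-range intensities out of the
map; the 50% threshold is the natural "this voxel is mostly brain
parenchyma" reading of using tissue location information. The binary map is
then convolved with a normalized cubic 5×5×5 box kernel (weight $1/125$,
zero padding), turning a noisy indicator into the local boundary-tissue
volume fraction in [0, 1] — the gwBTV map. Multiplying by the voxel volume
gives mm³.

**3. Normative Z-score (gwBZ).** The convolved maps of the cognitively
normal (CN) controls give voxelwise mean and sample-SD maps; each subject
is standardized as $z = (x - \mu_{CN})/\sigma_{CN}$. Boundary *loss* is
negative. Maps are smoothed with an 8 mm isotropic FWHM Gaussian before any
statistics.

### The Z-score sign

The verbal description of the subtraction ("individual subtracted from
mean") and the interpretation of the result ("negative means less boundary
than the control population") point in opposite directions. We implement
$(x - \mu_{CN})/\sigma_{CN}$, the convention under which reported
patient-group values are negative and the interpretation holds. This is a
deliberate design choice, not an oversight.

### Other readings we fixed

- *gwBTV definition.* "Boundary tissue volume at the area of gwBB" could
  also mean convolving $(f_{GM}+f_{WM})\cdot\mathrm{gwBB}$. We implement
  the convolved indicator itself: its [0, 1] range matches the magnitude of
  published ROI values, and for a single feature any monotone reweighting
  leaves ROC-based conclusions unchanged.
- *Band edges inclusive.* Measure-zero effect on continuous data; fixed for
  determinism.
- *Pool rule strict* (`> 0.5`): ties at exactly 0.5 are excluded.
- *Sample SD* (n−1) everywhere, matching mainstream statistics software.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| box kernel | 5×5×5 | voxels | the published map construction; `kernelSize = 1` is the identity |
| smoothing FWHM | 8 | mm | standard neuroimaging smoothing before voxel statistics; σ = FWHM/2.3548 |
| FDR level | 0.01 | — | voxelwise significance level |
| cluster extent | 100 | voxels | minimum contiguous cluster size |
| connectivity | 18 | — | face+edge neighbors, the convention of the major voxelwise-statistics packages; 6 and 26 available |
| SD floor | 1e-6 | density units | voxels where controls have (numerically) no variance carry no usable norm; z is set to 0 there |
| ANCOVA covariates | age, TIV | years, cm³ | additive covariate adjustment |

Total intracranial volume is the sum of all tissue fractions times voxel
volume, in cm³.

## What the phantom generator emulates — and what it does not

The generator builds nested-ellipsoid brains: WM core (default spherical,
12 mm radius), GM shell (5 mm), CSF surround (2 mm), on a 40³ grid of 1 mm
voxels. Ground-truth partial-volume fractions are computed by subvoxel
supersampling of the exact geometry (default 3× per axis; the estimate
converges monotonically to the analytic volume as the factor grows) and
are returned *unblurred*, so segmentation accuracy can be scored against
geometry rather than against the degraded image.

Disease severity has four knobs per subject:

- `contrastScale` ∈ (0, 1]: multiplies the WM−GM intensity gap. This is
  the primary disease model — the threshold band provably narrows with it.
- `boundaryBlur` (mm): Gaussian blur of the noiseless intensity. Blur
  *widens* the spatial extent of intermediate intensities and empirically
  *increases* boundary density on these phantoms, i.e. it has no monotone
  relationship with severity in the direction one might expect. The cohort
  defaults therefore hold blur at 0.5 ± 0.1 mm for every group, so that
  group differences flow through the contrast channel whose direction the
  measurement model predicts.
- `atrophy` (mm): thins the GM shell (error when it would eliminate it).
- `noiseSD`: additive Gaussian noise, applied last under the subject seed.
  Rician noise is not modeled; the pipeline consumes relative intensities
  only.

Cohort defaults emulate a three-group memory-clinic study: 62/72/93
subjects (CN/MCI/AD); ages 71.8 ± 4.8, 72.6 ± 5.1, 73.6 ± 7.7 years; CDR
fixed at 0/0.5/1; contrast means 1.0/0.9/0.5; and a K-MMSE model
`27.4 − 16·(1 − contrastScale) + N(0, 2)` clipped to [0, 30], whose
coefficients reproduce group cognition means of about 27.4/25.8/19.4.
Age affects only the covariate table, not the image geometry, which keeps
covariate-adjustment tests interpretable — but it also means age-map
correlations in synthetic runs arise solely through group membership and
are weaker than in clinical data, where aging itself degrades contrast.

Not emulated: cortical folding, template registration and its residual
misalignment, bias fields, scanner artifacts, and any quantitative
calibration of effect sizes to clinical populations. Passing tests on
phantoms therefore validate the *computational pipeline* (algebra,
invariances, directionality, error control), not clinical effect-size
claims.

## Numerical choices

- **Segmentation.** The built-in 3-class univariate Gaussian-mixture EM
  uses deterministic quantile initialization (means at the 1/6, 3/6, 5/6
  in-mask quantiles), log-space responsibilities, a 1e-6 variance floor,
  and stops when the relative log-likelihood change falls below 1e-8
  (default cap 200 iterations, with a warning and a flagged result on
  non-convergence). Components map to CSF/GM/WM by ascending mean — the T1
  contrast order. Free means, variances and weights; no equal-variance
  constraint. Pass-through mode skips estimation when fraction volumes are
  supplied.
- **Convolution.** Both the box filter and Gaussian smoothing are
  separable 1D passes. The box filter uses zero padding (density stays a
  mean over exactly $k^3$ cells; total mass is conserved whenever the
  boundary support keeps a half-kernel margin from the grid edge, as brain
  maps with a background border do). Smoothing uses reflect padding with
  the kernel truncated at 4σ and renormalized, so constants are preserved
  exactly and the operator is linear to machine precision.
- **Degenerate inputs.** A threshold band with `lower >= upper` yields an
  all-zero gwBB with a warning; an ROI with no voxels is flagged missing;
  constant features give AUC 0.5; perfect separation in logistic models is
  flagged while probabilities and AUC are still returned; zero-variance
  voxels are excluded from the normative valid mask.
- **Cluster ties and ordering.** Clusters are reported by descending size;
  Youden-optimal ROC ties resolve to the lowest threshold.
- **Post-hoc scheme.** Pairwise group contrasts are taken inside the full
  ANCOVA model (shared residual variance) and Bonferroni-multiplied by 3.
- **CDR as numeric.** CDR is ordinal, but biomarker-combination models
  treat it as a numeric feature, matching how such combinations are
  usually reported; with only one CDR level per synthetic group it
  separates groups perfectly, and such fits carry a `separation` flag.
- **Leave-one-out.** By default controls are scored against the model that
  includes them (so the control cohort has exactly mean 0, SD 1 per voxel —
  an identity the tests assert to 1e-10); `zscoreCohort(loo = TRUE)`
  provides the unbiased variant.
- **Determinism.** One root seed drives cohort covariates, severities, and
  per-subject noise seeds (drawn once, below 2³¹); reruns are
  checksum-identical, which the test suite verifies on a demo pipeline.

## Problem sizes in the test suite

Unit tests run on 12³ phantoms and small random grids; end-to-end property
checks use the default 40³ geometry with cohorts of 10 per group, a
500-replicate type-I simulation at n = 60, ROC closed-form checks at
n = 200/200 (averaged over 10 replicates to keep Monte-Carlo error small
relative to the 0.03 comparison band), and a planted-signal voxel
inference with 15 subjects per group. `scripts/acceptance.R` runs the full
62/72/93 cohort. These sizes were chosen to make every stochastic check
stable at fixed seeds while keeping a full run in the minutes range on one
CPU.

## Known limitations

- No spatial normalization: all inputs must already share a common space;
  the package errors on grid/spacing/space-tag mismatches (spacing
  tolerance 1e-6 relative) rather than resampling.
- The normative model is unadjusted for covariates (no age-regressed
  norms) and uses the plain sample SD, not robust estimators.
- The "others" (non-brain) tissue class is not modeled; fractions are
  normalized over GM/WM/CSF, and TIV sums those three.
- Voxelwise TIV adjustment is additive (covariate in the GLM), not
  proportional scaling.
- Three-group classification is implemented as three pairwise binary
  problems; no multi-class ROC surfaces.
- Phantom effect sizes are free parameters of the synthetic model, not
  estimates of clinical effects.
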