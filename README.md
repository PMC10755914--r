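# gwboundary

Mapping and statistics for **gray-white matter boundary degradation** on
spatially normalized T1-weighted brain MRI. In Alzheimer's disease the
transition zone between cortical gray matter (GM) and subcortical white
matter (WM) blurs: the T1 intensity contrast across the interface collapses.
`gwboundary` quantifies this with two voxelwise biomarkers:

- **gwBB** — the binary gray-white boundary map. Per subject, two intensity
  thresholds are derived from the partial-volume tissue pools:

  ```
  lower = mean(SI | f_GM > 0.5) + SD(SI | f_GM > 0.5)
  upper = mean(SI | f_WM > 0.5) − SD(SI | f_WM > 0.5)
  ```

  (the mean ± half of the 2·SD dispersion of each pool). Voxels carrying
  predominantly GM/WM tissue (`f_GM + f_WM > 0.5`) whose intensity lies in
  `[lower, upper]` are boundary (1), all others 0.
- **gwBTV** — the boundary tissue volume map: gwBB convolved with a
  normalized 5×5×5 box kernel, i.e. the local boundary-tissue volume
  fraction in [0, 1].
- **gwBZ** — the boundary Z-score map: each subject's gwBTV map
  standardized voxelwise against the mean/SD maps of a cognitively normal
  (CN) control cohort, `z = (individual − mean_CN) / SD_CN`. Boundary loss
  is negative.

Around the core maps the package provides a 3-class Gaussian-mixture tissue
segmenter (or pass-through of externally computed fractions), total
intracranial volume, 8 mm FWHM Gaussian smoothing, ROI statistics (ANCOVA
with age and TIV as covariates with Bonferroni post-hoc tests, Pearson
correlation with age, partial correlation with cognition adjusted for age
and TIV), voxelwise GLMs with Benjamini-Hochberg FDR and cluster-extent
filtering (100 voxels, 18-connectivity), and logistic-regression biomarker
combination with ROC analysis (AUC, Youden operating point, DeLong test).

Because clinical cohorts of this kind are not publicly deposited, the
package ships a **synthetic phantom cohort generator**: nested-ellipsoid
brains (WM core, GM shell, CSF surround) with exact supersampled
partial-volume ground truth, per-subject contrast collapse, boundary blur,
atrophy and noise, and covariates (age, K-MMSE, CDR) tied to planted
disease severity. Every stage is validated against brute-force oracles and
closed forms on these phantoms.

## Worked example

```r
library(gwboundary)

cfg <- pipelineConfig(
  outputDir = "gwb-demo",
  phantom = phantomSpec(),                            # 40^3 grid, 1 mm voxels
  cohort  = cohortSpec(nPerGroup = c(CN = 10, MCI = 10, AD = 10)),
  seed    = 42)
res <- runPipeline(cfg)

subset(res$groupAncova, roi == "boundary_shell" & map == "gwBZ",
       select = c(F, p, mean_CN, mean_MCI, mean_AD))
#>          F          p      mean_CN   mean_MCI    mean_AD
#> 1 3.337461 0.05725619 1.179612e-16 -0.6389253 -0.7573240

subset(res$correlations, roi == "boundary_shell")
#>     map            roi      r_age     p_age   r_kmmse   p_kmmse
#> 1  gwBZ boundary_shell -0.1869864 0.3816314 0.1743616 0.4377116
#> 4 gwBTV boundary_shell -0.1877167 0.3797413 0.2053553 0.3592462

subset(res$classification, pair == "CN vs AD" & features == "gwBZ")
#>   features     pair  SE SP      AUC            p separation
#> 2     gwBZ CN vs AD 100 75 0.890625 9.026031e-06      FALSE
```

Reading: controls are centered at gwBZ 0 by construction; MCI and AD
subjects sit progressively below it (boundary loss), gwBZ correlates
negatively with age and positively with K-MMSE across the cohort, and the
boundary-shell gwBZ mean separates AD from CN with AUC ≈ 0.89 at the
Youden operating point (sensitivity 100%, specificity 75%). The output
directory holds the per-subject NIfTI maps, the normative model, cluster
tables and a checksum manifest; reruns under one seed are bit-identical.

Individual stages are available as plain functions (`makePhantom`,
`segmentGMM`, `computeThresholds`, `computeGWBB`, `boxConvolve`,
`buildNormative`, `zscoreMap`, `gaussianSmooth`, `roiMeans`, `ancovaGroup`,
`partialCorr`, `voxelGLM`, `clusterThreshold`, `logisticRoc`).

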