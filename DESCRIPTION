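Package: gwboundary
Title: Gray-White Matter Boundary Z-Score and Boundary Tissue Volume Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps the gray-white matter boundary on spatially normalized
    T1-weighted brain volumes and quantifies its degradation. Per-subject
    intensity thresholds derived from gray- and white-matter partial-volume
    pools define a binary boundary map (gwBB); a 5x5x5 box convolution turns
    it into a local boundary tissue volume fraction map (gwBTV); voxelwise
    normative mean/SD maps from cognitively normal controls standardize each
    subject into a boundary Z-score map (gwBZ). Includes a 3-class Gaussian
    mixture tissue segmenter, FWHM Gaussian smoothing, ROI and voxelwise group
    statistics (ANCOVA with covariates, partial and Pearson correlations,
    Benjamini-Hochberg FDR with cluster-extent filtering), logistic-regression
    biomarker combination with ROC analysis, and a synthetic ellipsoid brain
    phantom cohort generator with known partial-volume ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
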