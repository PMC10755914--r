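# Synthetic brain phantoms: a WM-core ellipsoid wrapped in a GM shell and a
# thin CSF surround, with subvoxel partial-volume ground truth obtained by
# supersampling. Disease is modeled primarily as collapse of the gray-white
# intensity contrast, which provably narrows the threshold band the binary
# boundary map is built from; geometric blur, GM atrophy and noise are
# additional severity knobs.

#' Phantom geometry and intensity specification
#'
#' Defines the ellipsoid brain: a WM core with the given semi-axes, a GM
#' shell of constant thickness around it, and a CSF surround. Nominal tissue
#' signal levels are in arbitrary T1-like units and must be strictly
#' increasing CSF < GM < WM. `supersample` is the integer subvoxel sampling
#' factor per axis used to compute partial-volume fractions; higher values
#' converge to the exact geometric fractions.
#'
#' @param gridShape integer(3), voxel counts per axis.
#' @param voxelSize numeric(3), spacing in mm (> 0).
#' @param wmSemiaxes numeric(3), WM-core ellipsoid semi-axes in mm.
#' @param gmThickness GM shell thickness in mm (> 0).
#' @param csfThickness CSF surround thickness in mm.
#' @param intensities named numeric: nominal `csf`, `gm`, `wm` signal levels.
#' @param supersample integer >= 1, subvoxel sampling factor per axis.
#' @param spaceTag common-space identifier attached to generated volumes.
#' @return A `PhantomSpec` (list) for use with [makePhantom()], [makeCohort()]
#'   and [makeToyAtlas()].
#' @examples
#' spec <- phantomSpec(gridShape = c(24, 24, 24), wmSemiaxes = c(7, 7, 7),
#'                     gmThickness = 3, supersample = 2)
#' ph <- makePhantom(spec, diseaseSeverity(), seed = 1)
#' @export
phantomSpec <- function(gridShape = c(40, 40, 40),
                        voxelSize = c(1, 1, 1),
                        wmSemiaxes = c(12, 12, 12),
                        gmThickness = 5,
                        csfThickness = 2,
                        intensities = c(csf = 40, gm = 100, wm = 160),
                        supersample = 3L,
                        spaceTag = "phantom") {
  gridShape <- as.integer(rep(gridShape, length.out = 3))
  voxelSize <- rep(as.numeric(voxelSize), length.out = 3)
  wmSemiaxes <- rep(as.numeric(wmSemiaxes), length.out = 3)
  stopifnot(all(gridShape >= 4L), all(voxelSize > 0), all(wmSemiaxes > 0),
            gmThickness > 0, csfThickness >= 0, supersample >= 1)
  if (!(intensities[["csf"]] < intensities[["gm"]] &&
        intensities[["gm"]] < intensities[["wm"]]))
    stop("intensities must be strictly increasing CSF < GM < WM")
  structure(list(gridShape = gridShape, voxelSize = voxelSize,
                 wmSemiaxes = wmSemiaxes, gmThickness = gmThickness,
                 csfThickness = csfThickness, intensities = intensities,
                 supersample = as.integer(supersample), spaceTag = spaceTag),
            class = "PhantomSpec")
}

#' Disease severity parameters for a phantom subject
#'
#' @param contrastScale multiplier in (0,1\] applied to the WM-GM intensity
#'   gap; 1 = full contrast, smaller = boundary contrast collapse.
#' @param boundaryBlur standard deviation in mm of geometric boundary blur
#'   (Gaussian filtering of the noiseless intensity).
#' @param atrophy reduction of the GM shell thickness in mm.
#' @param noiseSD additive Gaussian noise standard deviation, intensity units.
#' @return A `DiseaseSeverity` (list).
#' @export
diseaseSeverity <- function(contrastScale = 1, boundaryBlur = 0,
                            atrophy = 0, noiseSD = 0) {
  stopifnot(contrastScale > 0, contrastScale <= 1,
            boundaryBlur >= 0, atrophy >= 0, noiseSD >= 0)
  structure(list(contrastScale = contrastScale, boundaryBlur = boundaryBlur,
                 atrophy = atrophy, noiseSD = noiseSD),
            class = "DiseaseSeverity")
}

# Squared normalized ellipsoid radius at every grid point. With supersample
# s, returns the (s*n)^3 fine grid; fine-cell centers subdivide each voxel.
.ellipsoidRho2 <- function(gridShape, voxelSize, semiaxes, supersample = 1L) {
  center <- gridShape * voxelSize / 2
  ax2 <- vector("list", 3)
  for (a in 1:3) {
    nf <- gridShape[a] * supersample
    pos <- (seq_len(nf) - 0.5) * voxelSize[a] / supersample
    ax2[[a]] <- ((pos - center[a]) / semiaxes[a])^2
  }
  outer(outer(ax2[[1]], ax2[[2]], "+"), ax2[[3]], "+")
}

# Average an (s*n1, s*n2, s*n3) fine array down to (n1, n2, n3) voxel blocks.
.blockMean <- function(x, gridShape, s) {
  if (s == 1L) return(array(x, dim = gridShape))
  dim(x) <- c(s, gridShape[1], s, gridShape[2], s, gridShape[3])
  x <- aperm(x, c(1, 3, 5, 2, 4, 6))
  dim(x) <- c(s^3, prod(gridShape))
  array(colMeans(x), dim = gridShape)
}

# GM-outer and brain-outer semi-axes implied by a spec and severity.
.phantomRadii <- function(spec, severity = NULL) {
  atrophy <- if (is.null(severity)) 0 else severity$atrophy
  if (atrophy >= spec$gmThickness) stop("GM shell eliminated")
  list(wm = spec$wmSemiaxes,
       gmOuter = spec$wmSemiaxes + (spec$gmThickness - atrophy),
       brainOuter = spec$wmSemiaxes + (spec$gmThickness - atrophy) + spec$csfThickness)
}

#' Generate one synthetic brain phantom
#'
#' Partial-volume fractions are the supersampled geometric memberships of
#' the nested ellipsoids (WM core, GM shell, CSF surround), averaged per
#' voxel. The noiseless intensity is
#' `f_CSF*I_CSF + f_GM*I_GM' + f_WM*I_WM` with
#' `I_GM' = I_WM - contrastScale*(I_WM - I_GM)`, then Gaussian-blurred by
#' `boundaryBlur` mm, then additive Gaussian noise is applied under `seed`.
#' The returned ground-truth fractions are the unblurred geometric ones.
#'
#' @param spec a [phantomSpec()].
#' @param severity a [diseaseSeverity()].
#' @param seed integer RNG seed for the noise draw.
#' @return A list with elements `volume` ([BrainVolume-class]) and
#'   `fractions` ([TissueFractions-class]).
#' @export
makePhantom <- function(spec, severity = diseaseSeverity(), seed = 1L) {
  stopifnot(inherits(spec, "PhantomSpec"), inherits(severity, "DiseaseSeverity"))
  radii <- .phantomRadii(spec, severity)
  s <- spec$supersample
  inWM <- .ellipsoidRho2(spec$gridShape, spec$voxelSize, radii$wm, s) <= 1
  inGMo <- .ellipsoidRho2(spec$gridShape, spec$voxelSize, radii$gmOuter, s) <= 1
  inBr <- .ellipsoidRho2(spec$gridShape, spec$voxelSize, radii$brainOuter, s) <= 1

  fWM <- .blockMean(inWM, spec$gridShape, s)
  fGMo <- .blockMean(inGMo, spec$gridShape, s)
  fBr <- .blockMean(inBr, spec$gridShape, s)
  fGM <- fGMo - fWM
  fCSF <- fBr - fGMo

  ints <- spec$intensities
  gmLevel <- ints[["wm"]] - severity$contrastScale * (ints[["wm"]] - ints[["gm"]])
  intensity <- fCSF * ints[["csf"]] + fGM * gmLevel + fWM * ints[["wm"]]

  if (severity$boundaryBlur > 0)
    intensity <- .gaussFilter3D(intensity, severity$boundaryBlur / spec$voxelSize)

  set.seed(as.integer(seed))
  intensity <- intensity + array(stats::rnorm(length(intensity), 0, severity$noiseSD),
                                 dim = spec$gridShape)

  list(volume = brainVolume(intensity, spec$voxelSize, spec$spaceTag),
       fractions = tissueFractions(fGM, fWM, fCSF, spec$voxelSize, spec$spaceTag))
}

#' Toy ROI atlas for the phantom geometry
#'
#' Three disjoint ROIs defined on the nominal (un-atrophied) geometry:
#' label 1 `boundary_shell` (voxel centers within +/- `shellHalfWidth` mm of
#' the nominal GM/WM interface), label 2 `gm_shell` (remaining GM shell),
#' label 3 `wm_core` (remaining WM core). Label 0 is background. Distance to
#' the interface is measured as `(rho - 1) * min(wmSemiaxes)` where `rho` is
#' the normalized ellipsoid radius; exact for a spherical core.
#'
#' @param spec a [phantomSpec()].
#' @param shellHalfWidth half-width of the boundary shell in mm.
#' @return An [ROIAtlas-class] with ROIs `boundary_shell`, `gm_shell`,
#'   `wm_core`.
#' @export
makeToyAtlas <- function(spec, shellHalfWidth = 2) {
  stopifnot(inherits(spec, "PhantomSpec"))
  radii <- .phantomRadii(spec)
  rho <- sqrt(.ellipsoidRho2(spec$gridShape, spec$voxelSize, radii$wm, 1L))
  rhoGMo <- sqrt(.ellipsoidRho2(spec$gridShape, spec$voxelSize, radii$gmOuter, 1L))
  dist <- (rho - 1) * min(spec$wmSemiaxes)
  labels <- array(0L, spec$gridShape)
  labels[abs(dist) <= shellHalfWidth] <- 1L
  labels[labels == 0L & dist > shellHalfWidth & rhoGMo <= 1] <- 2L
  labels[labels == 0L & dist < -shellHalfWidth] <- 3L
  roiAtlas(labels,
           c("1" = "boundary_shell", "2" = "gm_shell", "3" = "wm_core"),
           voxelSize = spec$voxelSize, spaceTag = spec$spaceTag)
}

#' Cohort-level simulation specification
#'
#' Group sizes, per-group severity distributions, and covariate models. The
#' defaults emulate the study conditions of a three-group memory-clinic
#' cohort: group sizes 62/72/93 (CN/MCI/AD), group ages 71.8 +/- 4.8,
#' 72.6 +/- 5.1 and 73.6 +/- 7.7 years, a cognition score (K-MMSE, 0-30)
#' that declines linearly with planted gray-white contrast loss
#' (intercept 27.4, slope -16, noise SD 2, reproducing group means
#' 27.4/25.8/19.4 for contrast means 1.0/0.9/0.5), and fixed CDR 0/0.5/1.
#'
#' Each severity entry is a list with `contrast`, `blur`, `atrophy` given as
#' `c(mean, sd)` in their natural units and a scalar `noiseSD`; subject
#' values are drawn Gaussian and clipped to the valid ranges.
#'
#' @param nPerGroup named integer vector, subjects per group (CN/MCI/AD).
#' @param severityByGroup per-group severity distributions (see Details).
#' @param ageModel per-group `c(mean, sd)` of age in years.
#' @param kmmseModel list(intercept, slope, sd, clip); slope applies to
#'   contrast loss `1 - contrastScale`.
#' @param cdrByGroup named numeric, fixed CDR per group.
#' @param seed integer root seed for all cohort randomness.
#' @return A `CohortSpec` (list) for [makeCohort()].
#' @export
cohortSpec <- function(nPerGroup = c(CN = 62, MCI = 72, AD = 93),
                       severityByGroup = list(
                         CN = list(contrast = c(1.0, 0.02), blur = c(0.5, 0.1),
                                    atrophy = c(0, 0), noiseSD = 2),
                         MCI = list(contrast = c(0.9, 0.05), blur = c(0.5, 0.1),
                                    atrophy = c(0.5, 0.2), noiseSD = 2),
                         AD = list(contrast = c(0.5, 0.08), blur = c(0.5, 0.1),
                                    atrophy = c(1.5, 0.3), noiseSD = 2)),
                       ageModel = list(CN = c(71.8, 4.8), MCI = c(72.6, 5.1),
                                       AD = c(73.6, 7.7)),
                       kmmseModel = list(intercept = 27.4, slope = -16,
                                         sd = 2, clip = c(0, 30)),
                       cdrByGroup = c(CN = 0, MCI = 0.5, AD = 1),
                       seed = 1L) {
  groups <- names(nPerGroup)
  stopifnot(!is.null(groups), all(nPerGroup >= 1),
            all(groups %in% names(severityByGroup)),
            all(groups %in% names(ageModel)),
            all(groups %in% names(cdrByGroup)),
            kmmseModel$clip[1] < kmmseModel$clip[2])
  structure(list(nPerGroup = nPerGroup, severityByGroup = severityByGroup,
                 ageModel = ageModel, kmmseModel = kmmseModel,
                 cdrByGroup = cdrByGroup, seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Simulate a phantom cohort
#'
#' Draws per-subject severity and covariates under the cohort seed, then
#' generates one phantom per subject. With `dir` set, writes per-subject
#' NIfTI volumes (`<id>_t1/gm/wm/csf.nii.gz`), the toy atlas and a cohort
#' CSV, and records the paths; otherwise keeps the volumes in memory. Output
#' is deterministic given the cohort seed.
#'
#' @param cohort a [cohortSpec()].
#' @param spec a [phantomSpec()].
#' @param dir optional output directory; created if needed.
#' @param keepVolumes keep generated volumes in the returned object
#'   (default: only when not writing to disk).
#' @return A `CohortManifest`: list with `table` (one row per subject:
#'   subject_id, group, age, kmmse, cdr, contrast_scale, boundary_blur_mm,
#'   atrophy_mm, noise_sd, tiv_cm3, and file paths when written), `subjects`
#'   (named list of [makePhantom()] outputs, or NULL), `atlas`, `spec`,
#'   `cohortSpec`.
#' @export
makeCohort <- function(cohort, spec, dir = NULL, keepVolumes = is.null(dir)) {
  stopifnot(inherits(cohort, "CohortSpec"), inherits(spec, "PhantomSpec"))
  groups <- names(cohort$nPerGroup)
  n <- sum(cohort$nPerGroup)

  set.seed(cohort$seed)
  group <- factor(rep(groups, cohort$nPerGroup), levels = groups)
  clip01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)

  contrast <- blur <- atrophy <- noiseSD <- age <- numeric(n)
  for (g in groups) {
    i <- which(group == g)
    sv <- cohort$severityByGroup[[g]]
    contrast[i] <- clip01(stats::rnorm(length(i), sv$contrast[1], sv$contrast[2]),
                          0.05, 1)
    blur[i] <- pmax(stats::rnorm(length(i), sv$blur[1], sv$blur[2]), 0)
    atrophy[i] <- clip01(stats::rnorm(length(i), sv$atrophy[1], sv$atrophy[2]),
                         0, 0.9 * spec$gmThickness)
    noiseSD[i] <- sv$noiseSD
    am <- cohort$ageModel[[g]]
    age[i] <- stats::rnorm(length(i), am[1], am[2])
  }
  km <- cohort$kmmseModel
  kmmse <- clip01(km$intercept + km$slope * (1 - contrast) +
                    stats::rnorm(n, 0, km$sd), km$clip[1], km$clip[2])
  cdr <- unname(cohort$cdrByGroup[as.character(group)])
  subjectSeeds <- sample.int(.Machine$integer.max - 1L, n)

  ids <- sprintf("sub%03d", seq_len(n))
  tab <- data.frame(subject_id = ids, group = as.character(group),
                    age = age, kmmse = kmmse, cdr = cdr,
                    contrast_scale = contrast, boundary_blur_mm = blur,
                    atrophy_mm = atrophy, noise_sd = noiseSD,
                    stringsAsFactors = FALSE)

  atlas <- makeToyAtlas(spec)
  subjects <- if (keepVolumes) stats::setNames(vector("list", n), ids) else NULL
  tiv <- numeric(n)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (ch in c("t1", "gm", "wm", "csf"))
      tab[[paste0(ch, "_path")]] <- file.path(dir, paste0(ids, "_", ch, ".nii.gz"))
  }

  for (s in seq_len(n)) {
    sev <- diseaseSeverity(contrast[s], blur[s], atrophy[s], noiseSD[s])
    ph <- makePhantom(spec, sev, seed = subjectSeeds[s])
    tiv[s] <- computeTIV(ph$fractions)
    if (!is.null(dir)) {
      writeVolume(ph$volume, tab$t1_path[s])
      writeVolume(ph$fractions@gm, tab$gm_path[s], spec$voxelSize)
      writeVolume(ph$fractions@wm, tab$wm_path[s], spec$voxelSize)
      writeVolume(ph$fractions@csf, tab$csf_path[s], spec$voxelSize)
    }
    if (keepVolumes) subjects[[s]] <- ph
  }
  tab$tiv_cm3 <- tiv

  if (!is.null(dir)) {
    writeVolume(atlas, file.path(dir, "atlas.nii.gz"))
    utils::write.csv(tab, file.path(dir, "cohort.csv"), row.names = FALSE)
  }

  structure(list(table = tab, subjects = subjects, atlas = atlas,
                 spec = spec, cohortSpec = cohort, dir = dir),
            class = "CohortManifest")
}

# Load one subject's volumes from a manifest (memory or disk).
.cohortSubject <- function(manifest, i) {
  if (!is.null(manifest$subjects))
    return(manifest$subjects[[i]])
  tab <- manifest$table
  tag <- manifest$spec$spaceTag
  t1 <- readVolume(tab$t1_path[i], tag)
  fr <- tissueFractions(as.array(volData(readVolume(tab$gm_path[i], tag))),
                        as.array(volData(readVolume(tab$wm_path[i], tag))),
                        as.array(volData(readVolume(tab$csf_path[i], tag))),
                        voxelSize = voxelSize(t1), spaceTag = tag)
  list(volume = t1, fractions = fr)
}
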