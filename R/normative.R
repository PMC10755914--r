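#' Build a control-cohort normative model of the convolved boundary
#'
#' Averages the convolved gwBB maps of the cognitively normal controls into
#' a voxelwise mean map and computes the voxelwise sample SD (n-1). Voxels
#' whose SD is at or below the floor are excluded from the valid mask;
#' Z-scores are defined only on the valid mask.
#'
#' @param densities list of [BoundaryDensityMap-class] from the control
#'   group; at least 2, common space, identical kernel size.
#' @param sdFloor SD floor below which a voxel is excluded (default 1e-6).
#' @return A [NormativeModel-class].
#' @seealso [zscoreMap()]
#' @export
buildNormative <- function(densities, sdFloor = 1e-6) {
  if (length(densities) < 2L) stop("need at least 2 control maps")
  stopifnot(all(vapply(densities, is, TRUE, "BoundaryDensityMap")))
  ks <- vapply(densities, function(d) d@kernelSize, integer(1))
  if (length(unique(ks)) != 1L)
    stop("mixed kernel sizes among control maps: ", paste(unique(ks), collapse = ", "))
  checkCommonSpace(densities)
  n <- length(densities)
  meanMap <- Reduce(`+`, lapply(densities, volData)) / n
  ss <- Reduce(`+`, lapply(densities, function(d) (volData(d) - meanMap)^2))
  sdMap <- sqrt(ss / (n - 1))
  new("NormativeModel", meanMap = meanMap, sdMap = sdMap,
      nControls = as.integer(n), validMask = sdMap > sdFloor,
      sdFloor = sdFloor, kernelSize = ks[1],
      voxelSize = voxelSize(densities[[1]]), spaceTag = spaceTag(densities[[1]]))
}

#' Per-subject boundary Z-score map (gwBZ)
#'
#' `z = (individual - control mean) / control SD` on the model's valid mask
#' and 0 elsewhere. With this sign convention, boundary loss relative to the
#' control population is negative.
#'
#' Scoring a control against a model built from all controls (itself
#' included) reuses the subject in the reference; see [zscoreCohort()] with
#' `loo = TRUE` for the unbiased leave-one-out variant.
#'
#' @param subject a [BoundaryDensityMap-class].
#' @param model a [NormativeModel-class] with matching kernel size.
#' @return A [ZScoreMap-class].
#' @export
zscoreMap <- function(subject, model) {
  stopifnot(is(subject, "BoundaryDensityMap"), is(model, "NormativeModel"))
  if (subject@kernelSize != model@kernelSize)
    stop(sprintf("kernel size mismatch: subject %d vs model %d",
                 subject@kernelSize, model@kernelSize))
  checkCommonSpace(list(subject, model))
  z <- array(0, dim(model@meanMap))
  v <- model@validMask
  z[v] <- (volData(subject)[v] - model@meanMap[v]) / model@sdMap[v]
  new("ZScoreMap", data = z, voxelSize = voxelSize(subject),
      spaceTag = spaceTag(subject), validMask = v)
}

#' Score a cohort of densities against a normative model
#'
#' Convenience wrapper: z-scores each density map, optionally leave-one-out
#' for maps that themselves entered the model.
#'
#' @param densities list of [BoundaryDensityMap-class].
#' @param model a [NormativeModel-class].
#' @param loo logical; when TRUE, each map is scored against a model rebuilt
#'   from the other control maps (unbiased variant). Requires `controls`.
#' @param controls the list of control densities the model was built from
#'   (needed for `loo = TRUE`).
#' @return list of [ZScoreMap-class].
#' @export
zscoreCohort <- function(densities, model, loo = FALSE, controls = NULL) {
  if (!loo) return(lapply(densities, zscoreMap, model = model))
  stopifnot(!is.null(controls))
  lapply(seq_along(densities), function(i) {
    rest <- controls[-i]
    zscoreMap(densities[[i]], buildNormative(rest, sdFloor = model@sdFloor))
  })
}

#' FWHM to Gaussian sigma
#'
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))` (~ fwhm / 2.35482).
#'
#' @param fwhm full width at half maximum.
#' @return sigma in the same units.
#' @export
fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Isotropic FWHM Gaussian smoothing
#'
#' Separable Gaussian filtering with per-axis
#' `sigma_vox = fwhmToSigma(fwhm) / voxelSize`, kernel truncated at
#' `truncate` sigmas and renormalized to sum 1, reflect boundary handling.
#' Constant inputs are preserved exactly. Applied to gwBZ and gwBTV maps
#' before all statistics (default 8 mm).
#'
#' @param v a [BrainVolume-class] (or subclass) or 3D array.
#' @param fwhm full width at half maximum in mm (> 0).
#' @param truncate kernel support in sigma units (default 4).
#' @param voxelSize spacing in mm when `v` is a bare array.
#' @return A [BrainVolume-class] (array in, array out).
#' @export
gaussianSmooth <- function(v, fwhm = 8, truncate = 4, voxelSize = c(1, 1, 1)) {
  stopifnot(fwhm > 0)
  isVol <- is(v, "BrainVolume")
  data <- if (isVol) volData(v) else v
  if (any(!is.finite(data))) stop("non-finite input voxels")
  sigmaVox <- fwhmToSigma(fwhm) / (if (isVol) voxelSize(v) else rep(voxelSize, length.out = 3))
  out <- .gaussFilter3D(data, sigmaVox, truncate)
  if (isVol) brainVolume(out, voxelSize(v), spaceTag(v)) else out
}
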