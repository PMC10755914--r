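#' @import methods
NULL

.checkGrid <- function(data, what = "data") {
  if (length(dim(data)) != 3L)
    return(sprintf("%s must be a 3D array (got %d dims)", what, length(dim(data))))
  NULL
}

.checkSpacing <- function(voxelSize) {
  if (length(voxelSize) != 3L || any(!is.finite(voxelSize)) || any(voxelSize <= 0))
    return("voxelSize must be 3 positive finite spacings in mm")
  NULL
}

#' BrainVolume: a 3D scalar grid in a common space
#'
#' The elementary container of the package: a 3D array of voxel values with
#' per-axis spacing in mm and a space tag identifying the common template
#' space. All cross-subject operations require their inputs to share grid
#' shape, spacing and space tag (see [checkCommonSpace()]); no world-affine
#' arithmetic is performed because inputs are assumed co-registered.
#'
#' @slot data 3D numeric array of voxel values.
#' @slot voxelSize numeric(3), per-axis voxel spacing in mm, all > 0.
#' @slot spaceTag character(1) identifier of the common space.
#'
#' @seealso [brainVolume()], [readVolume()], [writeVolume()]
#' @export
setClass("BrainVolume",
  representation(data = "array", voxelSize = "numeric", spaceTag = "character"),
  validity = function(object) {
    msg <- c(.checkGrid(object@data), .checkSpacing(object@voxelSize))
    if (length(object@spaceTag) != 1L) msg <- c(msg, "spaceTag must be length 1")
    if (length(msg)) msg else TRUE
  })

#' Construct a BrainVolume
#'
#' @param data 3D numeric array.
#' @param voxelSize per-axis spacing in mm (recycled to length 3).
#' @param spaceTag common-space identifier.
#' @return A [BrainVolume-class] object.
#' @examples
#' v <- brainVolume(array(0, c(4, 4, 4)))
#' voxelSize(v)
#' @export
brainVolume <- function(data, voxelSize = c(1, 1, 1), spaceTag = "phantom") {
  new("BrainVolume", data = data, voxelSize = rep(as.numeric(voxelSize), length.out = 3),
      spaceTag = as.character(spaceTag))
}

#' TissueFractions: per-voxel GM/WM/CSF partial-volume fractions
#'
#' Each tissue grid holds the fraction of the voxel occupied by that tissue,
#' in \[0,1\]; the three fractions sum to 1 inside the brain and to 0 outside.
#' The brain mask is the set of voxels with any tissue.
#'
#' @slot gm,wm,csf 3D arrays of fractions in \[0,1\].
#' @slot voxelSize numeric(3) spacing in mm.
#' @slot spaceTag character(1).
#' @seealso [tissueFractions()], [segmentGMM()], [computeTIV()]
#' @export
setClass("TissueFractions",
  representation(gm = "array", wm = "array", csf = "array",
                 voxelSize = "numeric", spaceTag = "character"),
  validity = function(object) {
    msg <- c(.checkGrid(object@gm, "gm"), .checkSpacing(object@voxelSize))
    if (!identical(dim(object@gm), dim(object@wm)) ||
        !identical(dim(object@gm), dim(object@csf)))
      msg <- c(msg, "gm/wm/csf grids must share dimensions")
    tot <- object@gm + object@wm + object@csf
    rng <- range(object@gm, object@wm, object@csf)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      msg <- c(msg, "fractions must lie in [0,1]")
    if (max(tot) > 1 + 1e-9)
      msg <- c(msg, "gm+wm+csf exceeds 1")
    if (length(msg)) msg else TRUE
  })

#' Construct a TissueFractions object
#'
#' @param gm,wm,csf 3D arrays of per-voxel tissue fractions.
#' @param voxelSize per-axis spacing in mm.
#' @param spaceTag common-space identifier.
#' @return A [TissueFractions-class] object.
#' @export
tissueFractions <- function(gm, wm, csf, voxelSize = c(1, 1, 1), spaceTag = "phantom") {
  new("TissueFractions", gm = gm, wm = wm, csf = csf,
      voxelSize = rep(as.numeric(voxelSize), length.out = 3),
      spaceTag = as.character(spaceTag))
}

#' ROIAtlas: integer-labeled region atlas
#'
#' Label 0 is reserved for background; every nonzero label must be named in
#' the label map.
#'
#' @slot labels 3D integer array of region labels.
#' @slot nameMap named character vector mapping label (as name) to ROI name.
#' @slot voxelSize numeric(3) spacing in mm.
#' @slot spaceTag character(1).
#' @seealso [roiAtlas()], [makeToyAtlas()], [roiMeans()]
#' @export
setClass("ROIAtlas",
  representation(labels = "array", nameMap = "character",
                 voxelSize = "numeric", spaceTag = "character"),
  validity = function(object) {
    msg <- c(.checkGrid(object@labels, "labels"), .checkSpacing(object@voxelSize))
    labs <- sort(unique(as.vector(object@labels)))
    labs <- labs[labs != 0]
    if (any(labs < 0)) msg <- c(msg, "labels must be >= 0")
    missing <- setdiff(as.character(labs), names(object@nameMap))
    if (length(missing))
      msg <- c(msg, paste("labels missing from nameMap:", paste(missing, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' Construct an ROIAtlas
#'
#' @param labels 3D integer array; 0 = background.
#' @param nameMap named character vector, names are label values.
#' @param voxelSize per-axis spacing in mm.
#' @param spaceTag common-space identifier.
#' @return An [ROIAtlas-class] object.
#' @export
roiAtlas <- function(labels, nameMap, voxelSize = c(1, 1, 1), spaceTag = "phantom") {
  storage.mode(labels) <- "integer"
  new("ROIAtlas", labels = labels, nameMap = nameMap,
      voxelSize = rep(as.numeric(voxelSize), length.out = 3),
      spaceTag = as.character(spaceTag))
}

#' ThresholdPair: per-subject boundary intensity band
#'
#' The lower threshold is the GM-pool mean plus half its 2SD dispersion
#' (i.e. mean + 1 SD); the upper threshold is the WM-pool mean minus half its
#' 2SD dispersion (mean - 1 SD). T1 intensities between the two bound the
#' gray-white transition zone. When lower >= upper the band is degenerate and
#' the resulting binary boundary map is empty.
#'
#' @slot lower,upper intensity thresholds.
#' @slot gmMean,gmTwoSD,wmMean,wmTwoSD the four pool statistics the
#'   thresholds are built from (TwoSD = 2 x sample SD).
#' @slot degenerate logical(1), TRUE when lower >= upper.
#' @seealso [computeThresholds()], [computeGWBB()]
#' @export
setClass("ThresholdPair",
  representation(lower = "numeric", upper = "numeric",
                 gmMean = "numeric", gmTwoSD = "numeric",
                 wmMean = "numeric", wmTwoSD = "numeric",
                 degenerate = "logical"),
  validity = function(object) {
    msg <- NULL
    if (object@gmTwoSD < 0 || object@wmTwoSD < 0)
      msg <- c(msg, "2SD terms must be >= 0")
    if (abs(object@lower - (object@gmMean + object@gmTwoSD / 2)) > 1e-8)
      msg <- c(msg, "lower must equal gmMean + gmTwoSD/2")
    if (abs(object@upper - (object@wmMean - object@wmTwoSD / 2)) > 1e-8)
      msg <- c(msg, "upper must equal wmMean - wmTwoSD/2")
    if (length(msg)) msg else TRUE
  })

#' BoundaryBinaryMap: the binary gray-white boundary map (gwBB)
#'
#' Value 1 marks voxels whose T1 intensity lies inside the subject's
#' threshold band and that carry predominantly GM/WM tissue (the eligibility
#' mask); all other voxels are 0.
#'
#' @slot eligibleMask 3D logical array of voxels where the band rule was
#'   evaluated (f_GM + f_WM > 0.5).
#' @seealso [computeGWBB()], [boxConvolve()]
#' @export
setClass("BoundaryBinaryMap", contains = "BrainVolume",
  representation(eligibleMask = "array"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@eligibleMask), dim(object@data)))
      msg <- c(msg, "eligibleMask must match data dimensions")
    if (!all(object@data %in% c(0, 1)))
      msg <- c(msg, "gwBB values must be 0 or 1")
    if (any(object@data[!object@eligibleMask] != 0))
      msg <- c(msg, "values outside eligibleMask must be 0")
    if (length(msg)) msg else TRUE
  })

#' BoundaryDensityMap: box-convolved gwBB (the gwBTV map)
#'
#' Each voxel holds the mean of the binary boundary map over the centered
#' kernel^3 neighborhood (zero padding outside the grid), i.e. the local
#' boundary-tissue volume fraction in \[0,1\]. Multiplying by the voxel
#' volume gives boundary tissue volume in mm^3.
#'
#' @slot kernelSize odd integer edge length of the box kernel.
#' @seealso [boxConvolve()], [buildNormative()], [zscoreMap()]
#' @export
setClass("BoundaryDensityMap", contains = "BrainVolume",
  representation(kernelSize = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@kernelSize) != 1L || object@kernelSize < 1L ||
        object@kernelSize %% 2L == 0L)
      msg <- c(msg, "kernelSize must be a single odd integer >= 1")
    rng <- range(object@data)
    if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12)
      msg <- c(msg, "density values must lie in [0,1]")
    if (length(msg)) msg else TRUE
  })

#' NormativeModel: control-cohort voxelwise mean/SD of the convolved boundary
#'
#' Built from the convolved gwBB maps of the cognitively normal controls.
#' The valid mask excludes voxels whose control SD is at or below the floor
#' (default 1e-6); Z-scores are defined only there.
#'
#' @slot meanMap,sdMap 3D arrays: voxelwise mean and sample SD (n-1).
#' @slot nControls integer count of control maps.
#' @slot validMask 3D logical array, sd > floor.
#' @slot sdFloor the SD floor used.
#' @slot kernelSize box kernel size of the source density maps (provenance).
#' @slot voxelSize,spaceTag common-space metadata.
#' @seealso [buildNormative()], [zscoreMap()]
#' @export
setClass("NormativeModel",
  representation(meanMap = "array", sdMap = "array", nControls = "integer",
                 validMask = "array", sdFloor = "numeric", kernelSize = "integer",
                 voxelSize = "numeric", spaceTag = "character"),
  validity = function(object) {
    msg <- c(.checkGrid(object@meanMap, "meanMap"), .checkSpacing(object@voxelSize))
    if (!identical(dim(object@meanMap), dim(object@sdMap)) ||
        !identical(dim(object@meanMap), dim(object@validMask)))
      msg <- c(msg, "meanMap/sdMap/validMask must share dimensions")
    if (min(object@sdMap) < 0) msg <- c(msg, "sdMap must be >= 0")
    if (object@nControls < 2L) msg <- c(msg, "need at least 2 controls")
    if (length(msg)) msg else TRUE
  })

#' ZScoreMap: per-subject boundary Z-score map (gwBZ)
#'
#' z = (individual - control mean) / control SD on the model's valid mask and
#' 0 elsewhere, so that boundary loss relative to the control population is
#' negative.
#'
#' @slot validMask 3D logical array inherited from the normative model.
#' @seealso [zscoreMap()]
#' @export
setClass("ZScoreMap", contains = "BrainVolume",
  representation(validMask = "array"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@validMask), dim(object@data)))
      msg <- c(msg, "validMask must match data dimensions")
    if (any(object@data[!object@validMask] != 0))
      msg <- c(msg, "values outside validMask must be 0")
    if (length(msg)) msg else TRUE
  })
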