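#' Accessors for volume-like objects
#'
#' `volData()` extracts the 3D array, `voxelSize()` the per-axis spacing in
#' mm, and `spaceTag()` the common-space identifier.
#'
#' @param x a volume-like object ([BrainVolume-class], [TissueFractions-class],
#'   [ROIAtlas-class], [NormativeModel-class] or a subclass).
#' @return `volData()`: a 3D array; `voxelSize()`: numeric(3); `spaceTag()`:
#'   character(1); `voxelVolume()`: scalar voxel volume in mm^3.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("spaceTag", function(x) standardGeneric("spaceTag"))

#' @rdname accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname accessors
#' @export
setMethod("volData", "BrainVolume", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("volData", "ROIAtlas", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("voxelSize", "BrainVolume", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("voxelSize", "TissueFractions", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("voxelSize", "ROIAtlas", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("voxelSize", "NormativeModel", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("spaceTag", "BrainVolume", function(x) x@spaceTag)

#' @rdname accessors
#' @export
setMethod("spaceTag", "TissueFractions", function(x) x@spaceTag)

#' @rdname accessors
#' @export
setMethod("spaceTag", "ROIAtlas", function(x) x@spaceTag)

#' @rdname accessors
#' @export
setMethod("spaceTag", "NormativeModel", function(x) x@spaceTag)

#' @rdname accessors
#' @export
setMethod("voxelVolume", "ANY", function(x) prod(voxelSize(x)))

#' Tissue fraction accessors
#'
#' Extract a single tissue fraction grid or the brain mask (voxels with any
#' tissue) from a [TissueFractions-class] object.
#'
#' @param x a [TissueFractions-class] object.
#' @param tissue one of "gm", "wm", "csf".
#' @return `tissueFraction()`: a 3D array of fractions; `brainMask()`: a 3D
#'   logical array.
#' @export
tissueFraction <- function(x, tissue = c("gm", "wm", "csf")) {
  tissue <- match.arg(tissue)
  slot(x, tissue)
}

#' @rdname tissueFraction
#' @export
brainMask <- function(x) (x@gm + x@wm + x@csf) > 0

#' Eligibility / validity mask accessors
#'
#' @param x a [BoundaryBinaryMap-class], [ZScoreMap-class] or
#'   [NormativeModel-class] object.
#' @return a 3D logical array.
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname validMask
#' @export
setMethod("validMask", "ZScoreMap", function(x) x@validMask)

#' @rdname validMask
#' @export
setMethod("validMask", "NormativeModel", function(x) x@validMask)

#' @rdname validMask
#' @export
setMethod("validMask", "BoundaryBinaryMap", function(x) x@eligibleMask)

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s %dx%dx%d, voxel %.3gx%.3gx%.3g mm, space '%s'\n",
              class(object), d[1], d[2], d[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3],
              object@spaceTag))
  cat(sprintf("  range [%.4g, %.4g]\n", min(object@data), max(object@data)))
})

setMethod("show", "BoundaryDensityMap", function(object) {
  callNextMethod()
  cat(sprintf("  box kernel %dx%dx%d\n",
              object@kernelSize, object@kernelSize, object@kernelSize))
})

setMethod("show", "TissueFractions", function(object) {
  d <- dim(object@gm)
  cat(sprintf("TissueFractions %dx%dx%d, voxel %.3gx%.3gx%.3g mm, space '%s'\n",
              d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
              object@voxelSize[3], object@spaceTag))
  cat(sprintf("  brain voxels: %d\n", sum(brainMask(object))))
})

setMethod("show", "ROIAtlas", function(object) {
  d <- dim(object@labels)
  cat(sprintf("ROIAtlas %dx%dx%d, %d ROIs: %s\n", d[1], d[2], d[3],
              length(object@nameMap), paste(object@nameMap, collapse = ", ")))
})

setMethod("show", "ThresholdPair", function(object) {
  cat(sprintf("ThresholdPair [%.4g, %.4g]%s\n", object@lower, object@upper,
              if (object@degenerate) " (degenerate band)" else ""))
  cat(sprintf("  GM pool mean %.4g, 2SD %.4g; WM pool mean %.4g, 2SD %.4g\n",
              object@gmMean, object@gmTwoSD, object@wmMean, object@wmTwoSD))
})

setMethod("show", "NormativeModel", function(object) {
  d <- dim(object@meanMap)
  cat(sprintf("NormativeModel %dx%dx%d from %d controls (kernel %d)\n",
              d[1], d[2], d[3], object@nControls, object@kernelSize))
  cat(sprintf("  valid voxels: %d (SD floor %.1g)\n",
              sum(object@validMask), object@sdFloor))
})
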