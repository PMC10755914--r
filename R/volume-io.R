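#' Read a 3D volume from a NIfTI file
#'
#' Reads a single-frame 3D NIfTI-1 image into a [BrainVolume-class]. Integer
#' data types are preserved (needed for atlases). Inputs are assumed already
#' co-registered to a common space; the space tag is attached, not checked
#' against the file header.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param spaceTag common-space identifier to attach.
#' @return A [BrainVolume-class].
#' @seealso [writeVolume()], [readAtlas()], [checkCommonSpace()]
#' @export
readVolume <- function(path, spaceTag = "phantom") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3D single-frame image, got %dD: %s", length(d), path))
  data <- as.array(img)
  data <- array(data, dim = dim(data))  # plain array, type preserved
  nbad <- sum(!is.finite(data))
  if (nbad > 0)
    stop(sprintf("%d non-finite voxel(s) in %s", nbad, path))
  brainVolume(data, voxelSize = RNifti::pixdim(img)[1:3], spaceTag = spaceTag)
}

#' Write a volume to a NIfTI file
#'
#' Float data are written as float64 and integer data as int32, so that a
#' write/read round trip is lossless.
#'
#' @param x a [BrainVolume-class], [ROIAtlas-class], or 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxelSize spacing in mm, used when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(x, path, voxelSize = c(1, 1, 1)) {
  if (is(x, "BrainVolume")) { data <- x@data; voxelSize <- x@voxelSize }
  else if (is(x, "ROIAtlas")) { data <- x@labels; voxelSize <- x@voxelSize }
  else data <- x
  dtype <- if (is.integer(data)) "int32" else "double"
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- voxelSize
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Read an integer-labeled ROI atlas
#'
#' @param path NIfTI file of integer labels, 0 = background.
#' @param nameMap named character vector mapping label to ROI name; defaults
#'   to `roi<label>` for each nonzero label found.
#' @param spaceTag common-space identifier.
#' @return An [ROIAtlas-class].
#' @export
readAtlas <- function(path, nameMap = NULL, spaceTag = "phantom") {
  v <- readVolume(path, spaceTag)
  labs <- v@data
  if (any(abs(labs - round(labs)) > 0))
    stop("atlas contains non-integer labels: ", path)
  storage.mode(labs) <- "integer"
  present <- sort(unique(as.vector(labs)))
  present <- present[present != 0L]
  if (is.null(nameMap)) {
    nameMap <- paste0("roi", present)
    names(nameMap) <- as.character(present)
  }
  roiAtlas(labs, nameMap, voxelSize = v@voxelSize, spaceTag = spaceTag)
}

#' Enforce the common-space contract
#'
#' All volumes entering a cross-subject operation must share grid shape,
#' voxel spacing (relative tolerance 1e-6) and space tag. Errors name the
#' first offending pair.
#'
#' @param volumes a list of volume-like objects (anything with `volData`-style
#'   dimensions, [voxelSize()] and [spaceTag()] methods).
#' @return Invisibly `TRUE` on success; otherwise an error.
#' @export
checkCommonSpace <- function(volumes) {
  stopifnot(length(volumes) >= 1L)
  dims <- function(v) {
    if (is(v, "TissueFractions")) dim(v@gm)
    else if (is(v, "ROIAtlas")) dim(v@labels)
    else if (is(v, "NormativeModel")) dim(v@meanMap)
    else dim(volData(v))
  }
  ref <- volumes[[1]]
  for (i in seq_along(volumes)[-1]) {
    v <- volumes[[i]]
    if (!identical(dims(ref), dims(v)))
      stop(sprintf("grid shape mismatch between volume 1 (%s) and volume %d (%s)",
                   paste(dims(ref), collapse = "x"), i, paste(dims(v), collapse = "x")))
    rel <- abs(voxelSize(v) - voxelSize(ref)) / voxelSize(ref)
    if (any(rel > 1e-6))
      stop(sprintf("voxel spacing mismatch between volume 1 and volume %d (max rel diff %.3g)",
                   i, max(rel)))
    if (!identical(spaceTag(ref), spaceTag(v)))
      stop(sprintf("space tag mismatch between volume 1 ('%s') and volume %d ('%s')",
                   spaceTag(ref), i, spaceTag(v)))
  }
  invisible(TRUE)
}
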