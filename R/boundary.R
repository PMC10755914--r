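#' Per-subject boundary intensity thresholds
#'
#' The GM pool is the set of T1 intensities at voxels with more than 50%
#' gray matter (`f_GM > 0.5`); the WM pool likewise for white matter. The
#' lower threshold is the GM pool mean plus half its 2SD dispersion and the
#' upper threshold is the WM pool mean minus half its 2SD dispersion (sample
#' SD, n-1 denominator):
#' `lower = mean_GM + SD_GM`, `upper = mean_WM - SD_WM`.
#' Intensities between the two characterize the gray-white transition zone.
#'
#' @param t1 a [BrainVolume-class].
#' @param fractions a [TissueFractions-class] in the same space.
#' @return A [ThresholdPair-class]. When `lower >= upper` the band is
#'   degenerate: a warning is issued and the resulting gwBB map is empty.
#' @seealso [computeGWBB()]
#' @export
computeThresholds <- function(t1, fractions) {
  stopifnot(is(t1, "BrainVolume"), is(fractions, "TissueFractions"))
  checkCommonSpace(list(t1, fractions))
  data <- volData(t1)
  gmPool <- data[fractions@gm > 0.5]
  wmPool <- data[fractions@wm > 0.5]
  if (length(gmPool) < 2L) stop("GM pool has fewer than 2 voxels")
  if (length(wmPool) < 2L) stop("WM pool has fewer than 2 voxels")
  gmMean <- mean(gmPool); gmTwoSD <- 2 * stats::sd(gmPool)
  wmMean <- mean(wmPool); wmTwoSD <- 2 * stats::sd(wmPool)
  lower <- gmMean + gmTwoSD / 2
  upper <- wmMean - wmTwoSD / 2
  degenerate <- lower >= upper
  if (degenerate)
    warning(sprintf("degenerate band: lower %.4g >= upper %.4g; gwBB will be empty",
                    lower, upper))
  new("ThresholdPair", lower = lower, upper = upper,
      gmMean = gmMean, gmTwoSD = gmTwoSD, wmMean = wmMean, wmTwoSD = wmTwoSD,
      degenerate = degenerate)
}

#' Binary gray-white boundary map (gwBB)
#'
#' Assigns 1 to voxels whose T1 intensity lies inside the threshold band
#' (inclusive on both ends) and 0 to the rest. The band rule is evaluated
#' only at voxels carrying predominantly GM/WM tissue
#' (`f_GM + f_WM > 0.5`, the eligibility mask), so CSF and background voxels
#' with band-range intensities cannot enter the boundary map.
#'
#' @param t1 a [BrainVolume-class].
#' @param fractions a [TissueFractions-class] in the same space.
#' @param thresholds a [ThresholdPair-class] from [computeThresholds()].
#' @return A [BoundaryBinaryMap-class].
#' @seealso [boxConvolve()]
#' @export
computeGWBB <- function(t1, fractions, thresholds) {
  stopifnot(is(t1, "BrainVolume"), is(fractions, "TissueFractions"),
            is(thresholds, "ThresholdPair"))
  checkCommonSpace(list(t1, fractions))
  data <- volData(t1)
  eligible <- (fractions@gm + fractions@wm) > 0.5
  if (thresholds@degenerate) {
    bb <- array(0, dim(data))
  } else {
    bb <- array(as.numeric(eligible & data >= thresholds@lower &
                             data <= thresholds@upper), dim(data))
  }
  new("BoundaryBinaryMap", data = bb, voxelSize = voxelSize(t1),
      spaceTag = spaceTag(t1), eligibleMask = eligible)
}

#' Box convolution of the binary boundary map (the gwBTV map)
#'
#' Convolves the gwBB map with a normalized cubic box kernel (default
#' 5x5x5, weight `1/kernelSize^3`, zero padding outside the grid). Each
#' output voxel is the mean of the binary boundary over the centered
#' neighborhood, i.e. the local boundary-tissue volume fraction in \[0,1\];
#' multiply by the voxel volume for mm^3. Zero padding conserves total mass:
#' `sum(density) * kernelSize^3 = sum(gwBB)`.
#'
#' @param x a [BoundaryBinaryMap-class], [BrainVolume-class] or 3D array.
#' @param kernelSize odd integer edge length; 1 is the identity.
#' @param voxelSize,spaceTag metadata when `x` is a bare array.
#' @return A [BoundaryDensityMap-class].
#' @export
boxConvolve <- function(x, kernelSize = 5L, voxelSize = c(1, 1, 1),
                        spaceTag = "phantom") {
  kernelSize <- as.integer(kernelSize)
  if (kernelSize < 1L || kernelSize %% 2L == 0L)
    stop("kernelSize must be an odd integer >= 1")
  if (is(x, "BrainVolume")) {
    data <- volData(x); voxelSize <- voxelSize(x); spaceTag <- spaceTag(x)
  } else data <- x
  stopifnot(length(dim(data)) == 3L)
  out <- .boxFilter3D(data, kernelSize)
  out[out < 0] <- 0
  out[out > 1] <- 1
  new("BoundaryDensityMap", data = out, voxelSize = voxelSize,
      spaceTag = spaceTag, kernelSize = kernelSize)
}
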