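# Voxelwise general linear model and cluster-extent inference. The same
# design used for the ROI ANCOVA / regressions is fit at every voxel at once
# by shared-design least squares; inference maps are then thresholded by
# BH-FDR over the analysis mask and filtered by cluster extent under a
# stated neighborhood connectivity.

#' Voxelwise GLM (ANCOVA F map or covariate-slope T map)
#'
#' Fits `y_v ~ group + covariates` (or `y_v ~ covariates`) by least squares
#' at every in-mask voxel with one shared design. With `groups` given, the
#' statistic is the partial F test of the group indicators (voxelwise
#' ANCOVA). With `slopeTerm` naming a covariate column, the statistic is the
#' t test of that covariate's slope adjusting for the others (voxelwise
#' multiple regression).
#'
#' @param maps list of subject maps ([BrainVolume-class] or 3D arrays), one
#'   per design row.
#' @param mask 3D logical analysis mask (e.g. the normative model's valid
#'   mask); default all voxels.
#' @param groups factor of group membership, or NULL.
#' @param covariates data.frame/matrix of numeric covariates, or NULL.
#' @param slopeTerm name of the covariate column to test when `groups` is
#'   NULL.
#' @return list: `stat` (3D array, 0 outside mask), `p` (3D array, 1 outside
#'   mask), `statistic` ("F" or "t"), `df`, `mask`.
#' @seealso [clusterThreshold()], [significantClusters()]
#' @export
voxelGLM <- function(maps, mask = NULL, groups = NULL, covariates = NULL,
                     slopeTerm = NULL) {
  n <- length(maps)
  arrays <- lapply(maps, function(m) if (is(m, "BrainVolume")) volData(m) else m)
  d <- dim(arrays[[1]])
  stopifnot(all(vapply(arrays, function(a) identical(dim(a), d), TRUE)))
  if (is.null(mask)) mask <- array(TRUE, d)
  Y <- vapply(arrays, function(a) a[mask], numeric(sum(mask)))
  Y <- t(Y)  # n x V

  covm <- .covariateMatrix(covariates, n)
  if (!is.null(groups)) {
    groups <- droplevels(as.factor(groups))
    stopifnot(length(groups) == n)
    Xg <- stats::model.matrix(~ groups)
    X <- cbind(Xg, covm)
    testCols <- 2:nlevels(groups)
    statistic <- "F"
  } else {
    stopifnot(!is.null(slopeTerm), slopeTerm %in% colnames(covm))
    X <- cbind(`(Intercept)` = 1, covm)
    testCols <- which(colnames(X) == slopeTerm)
    statistic <- "t"
  }
  p <- ncol(X)
  if (qr(X)$rank < p) stop("design is rank deficient")
  if (n <= p) stop("more design columns than subjects")

  XtXinv <- solve(crossprod(X))
  B <- XtXinv %*% crossprod(X, Y)
  RSS <- colSums((Y - X %*% B)^2)
  dfRes <- n - p

  statArr <- array(0, d)
  pArr <- array(1, d)
  if (statistic == "F") {
    X0 <- X[, -testCols, drop = FALSE]
    B0 <- solve(crossprod(X0), crossprod(X0, Y))
    RSS0 <- colSums((Y - X0 %*% B0)^2)
    q <- length(testCols)
    Fv <- ((RSS0 - RSS) / q) / (RSS / dfRes)
    statArr[mask] <- Fv
    pArr[mask] <- stats::pf(Fv, q, dfRes, lower.tail = FALSE)
    df <- c(q, dfRes)
  } else {
    se <- sqrt(RSS / dfRes * XtXinv[testCols, testCols])
    tv <- B[testCols, ] / se
    statArr[mask] <- tv
    pArr[mask] <- 2 * stats::pt(-abs(tv), dfRes)
    df <- dfRes
  }
  list(stat = statArr, p = pArr, statistic = statistic, df = df, mask = mask)
}

.connectivityOffsets <- function(connectivity = 18L) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  maxAbs <- switch(as.character(connectivity), "6" = 1L, "18" = 2L, "26" = 3L)
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) >= 1 & rowSums(abs(g)) <= maxAbs, , drop = FALSE]
}

# Connected-component labeling by frontier (breadth-first) flood fill with
# vectorized neighbor expansion.
.labelComponents <- function(mask, connectivity = 18L) {
  d <- dim(mask)
  idx <- which(mask)
  labels <- array(0L, d)
  if (length(idx) == 0L)
    return(list(labels = labels, sizes = integer(0)))
  pos <- arrayInd(idx, d)
  lookup <- array(0L, d)
  lookup[idx] <- seq_along(idx)
  offs <- .connectivityOffsets(connectivity)
  nOff <- nrow(offs)
  lab <- integer(length(idx))
  cur <- 0L
  for (s in seq_along(idx)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      fp <- pos[frontier, , drop = FALSE]
      nf <- nrow(fp)
      cand <- fp[rep(seq_len(nf), each = nOff), , drop = FALSE] +
        offs[rep(seq_len(nOff), nf), , drop = FALSE]
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
            cand[, 2] >= 1 & cand[, 2] <= d[2] &
            cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      ids <- lookup[cand]
      ids <- unique(ids[ids != 0L])
      ids <- ids[lab[ids] == 0L]
      lab[ids] <- cur
      frontier <- ids
    }
  }
  labels[idx] <- lab
  list(labels = labels, sizes = tabulate(lab, nbins = cur))
}

#' Cluster-extent thresholding of a significant-voxel mask
#'
#' Labels connected components of a boolean grid under the given
#' neighborhood connectivity (default 18: face and edge neighbors) and
#' removes components smaller than `minExtent` contiguous voxels (default
#' 100, the voxelwise inference setting).
#'
#' @param mask 3D logical array of supra-threshold voxels.
#' @param minExtent minimum cluster size in voxels.
#' @param connectivity one of 6, 18, 26.
#' @param stat optional 3D statistic array used to report cluster peaks.
#' @return list: `mask` (logical array of surviving voxels), `labels`
#'   (integer array; surviving clusters relabeled 1..k by descending size),
#'   `table` (data.frame: cluster, size, peak coordinates, peak stat; sorted
#'   by size descending).
#' @export
clusterThreshold <- function(mask, minExtent = 100L, connectivity = 18L,
                             stat = NULL) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  comp <- .labelComponents(mask, connectivity)
  keep <- which(comp$sizes >= minExtent)
  ord <- keep[order(comp$sizes[keep], decreasing = TRUE)]
  outLabels <- array(0L, dim(mask))
  outMask <- array(FALSE, dim(mask))
  rows <- vector("list", length(ord))
  for (j in seq_along(ord)) {
    sel <- comp$labels == ord[j]
    outLabels[sel] <- j
    outMask <- outMask | sel
    peak <- c(NA_integer_, NA_integer_, NA_integer_)
    peakStat <- NA_real_
    if (!is.null(stat)) {
      vi <- which(sel)
      pk <- vi[which.max(stat[vi])]
      peak <- arrayInd(pk, dim(mask))[1, ]
      peakStat <- stat[pk]
    }
    rows[[j]] <- data.frame(cluster = j, size = comp$sizes[ord[j]],
                            peak_x = peak[1], peak_y = peak[2], peak_z = peak[3],
                            peak_stat = peakStat)
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), size = integer(0), peak_x = integer(0),
               peak_y = integer(0), peak_z = integer(0), peak_stat = numeric(0))
  list(mask = outMask, labels = outLabels, table = table)
}

#' FDR + cluster-extent inference on a voxelwise GLM
#'
#' Converts the in-mask p map to BH-FDR adjusted values (over the analysis
#' mask only), thresholds at `alpha`, and applies the cluster-extent filter.
#'
#' @param fit result of [voxelGLM()].
#' @param alpha FDR level (default 0.01).
#' @param minExtent minimum cluster extent in voxels (default 100).
#' @param connectivity neighborhood connectivity (default 18).
#' @return list: `mask`, `labels`, `table` (as [clusterThreshold()]),
#'   `nSignificant` (voxels passing FDR before the extent filter).
#' @export
significantClusters <- function(fit, alpha = 0.01, minExtent = 100L,
                                connectivity = 18L) {
  pv <- fit$p[fit$mask]
  fdr <- bhFdr(pv, alpha)
  sig <- array(FALSE, dim(fit$p))
  sig[fit$mask] <- fdr$reject
  res <- clusterThreshold(sig, minExtent, connectivity, stat = fit$stat)
  res$nSignificant <- sum(fdr$reject)
  res
}
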