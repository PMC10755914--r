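#' Segment brain tissues with a 3-class Gaussian mixture
#'
#' Fits a univariate 3-component Gaussian mixture to in-mask T1 intensities
#' by EM (free means, variances and weights) and returns the posterior
#' responsibilities as partial-volume fractions. Components are sorted by
#' ascending mean and assigned CSF, GM, WM, the standard T1 contrast order.
#' Initialization is deterministic (component means at the in-mask intensity
#' quantiles 1/6, 3/6, 5/6); `seed` is accepted for interface stability with
#' stochastic initializers.
#'
#' When per-tissue fraction files are already available (e.g. from an
#' external segmenter, or the phantom generator's ground truth), skip this
#' step entirely and construct a [TissueFractions-class] directly
#' (pass-through mode).
#'
#' @param t1 a [BrainVolume-class].
#' @param mask 3D logical array of voxels to segment; default: voxels with
#'   intensity above zero.
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxIter maximum EM iterations; on non-convergence a warning is
#'   issued and the current estimate returned with `converged = FALSE`.
#' @param seed integer, reserved for stochastic initialization.
#' @return A list: `fractions` ([TissueFractions-class]), `logLik`
#'   (per-iteration observed-data log-likelihood trace, non-decreasing),
#'   `converged`, `means`, `sds`, `weights` (each ordered CSF, GM, WM).
#' @seealso [computeTIV()]
#' @export
segmentGMM <- function(t1, mask = NULL, tol = 1e-8, maxIter = 200L, seed = 1L) {
  stopifnot(is(t1, "BrainVolume"), tol > 0, maxIter >= 1)
  data <- volData(t1)
  if (is.null(mask)) mask <- data > 0
  stopifnot(identical(dim(mask), dim(data)))
  x <- data[mask]
  if (length(x) == 0L) stop("mask is empty")
  if (length(x) < 9L) stop("fewer in-mask voxels than 3 x number of classes")
  if (any(!is.finite(x))) stop("non-finite in-mask intensities")
  set.seed(as.integer(seed))

  K <- 3L
  mu <- as.numeric(stats::quantile(x, c(1, 3, 5) / 6, names = FALSE))
  sig <- rep(stats::sd(x) / 2, K)
  sig <- pmax(sig, 1e-6)
  w <- rep(1 / K, K)

  n <- length(x)
  logLik <- numeric(0)
  converged <- FALSE
  resp <- matrix(0, n, K)
  for (iter in seq_len(maxIter)) {
    # E-step in log space for stability
    lp <- vapply(1:K, function(k)
      log(w[k]) + stats::dnorm(x, mu[k], sig[k], log = TRUE), numeric(n))
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    logLik <- c(logLik, ll)
    resp <- exp(lp - lse)

    nk <- colSums(resp)
    mu <- colSums(resp * x) / nk
    sig <- sqrt(pmax(colSums(resp * (outer(x, mu, "-")^2)) / nk, 1e-12))
    w <- nk / n

    if (iter > 1L) {
      prev <- logLik[iter - 1L]
      if (abs(ll - prev) <= tol * (abs(prev) + .Machine$double.eps)) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged)
    warning(sprintf("EM did not converge in %d iterations", maxIter))

  ord <- order(mu)  # ascending mean: CSF, GM, WM
  resp <- resp[, ord, drop = FALSE]
  grids <- lapply(1:K, function(k) {
    g <- array(0, dim(data))
    g[mask] <- resp[, k]
    g
  })
  list(fractions = tissueFractions(gm = grids[[2]], wm = grids[[3]],
                                   csf = grids[[1]],
                                   voxelSize = voxelSize(t1),
                                   spaceTag = spaceTag(t1)),
       logLik = logLik, converged = converged,
       means = mu[ord], sds = sig[ord], weights = w[ord])
}

#' Total intracranial volume
#'
#' TIV is the summation of all brain tissue fractions (GM + WM + CSF) times
#' the voxel volume, reported in cm^3.
#'
#' @param fractions a [TissueFractions-class].
#' @return TIV in cm^3.
#' @export
computeTIV <- function(fractions) {
  stopifnot(is(fractions, "TissueFractions"))
  sum(fractions@gm + fractions@wm + fractions@csf) * voxelVolume(fractions) / 1000
}
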