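# Separable 3D filtering primitives. Both the box filter behind the gwBTV map
# and FWHM Gaussian smoothing reduce to 1D convolutions applied along each
# axis; the heavy lifting is a single shifted-slab accumulation that touches
# the whole array once per kernel tap.

# Convolve a 3D array along one axis with a centered odd-length kernel.
# pad = "zero": values outside the grid are 0 (used by the box filter so the
# density stays a mean over exactly kernel^3 cells and total mass is
# conserved). pad = "reflect": mirror boundary (a b c | c b a), folding for
# supports wider than the grid (used by Gaussian smoothing so constants are
# preserved exactly).
.convolveAxis <- function(x, kernel, axis, pad = c("zero", "reflect")) {
  pad <- match.arg(pad)
  k <- length(kernel)
  stopifnot(k %% 2L == 1L)
  if (k == 1L) return(x * kernel)
  h <- (k - 1L) %/% 2L
  d <- dim(x)
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  n <- d[axis]
  m <- matrix(xp, nrow = n)

  if (pad == "zero") {
    z <- matrix(0, h, ncol(m))
    mp <- rbind(z, m, z)
  } else {
    # reflect: index i in 1-h .. n+h mapped by folding over period 2n
    idx <- seq.int(1L - h, n + h)
    j <- (idx - 1L) %% (2L * n)
    j <- ifelse(j < n, j + 1L, 2L * n - j)
    mp <- m[j, , drop = FALSE]
  }

  out <- matrix(0, n, ncol(m))
  for (t in seq_len(k))
    out <- out + kernel[t] * mp[t:(t + n - 1L), , drop = FALSE]

  res <- array(out, dim = d[perm])
  aperm(res, order(perm))
}

# Mean filter over a centered k^3 cube with zero padding.
.boxFilter3D <- function(x, k) {
  kern <- rep(1 / k, k)
  for (ax in 1:3) x <- .convolveAxis(x, kern, ax, pad = "zero")
  x
}

# Truncated, renormalized 1D Gaussian kernel in voxel units.
.gaussKernel <- function(sigmaVox, truncate = 4) {
  if (sigmaVox <= 0) return(1)
  h <- max(1L, as.integer(ceiling(truncate * sigmaVox)))
  g <- exp(-0.5 * ((-h:h) / sigmaVox)^2)
  g / sum(g)
}

# Separable Gaussian with per-axis sigma in voxel units, reflect padding.
.gaussFilter3D <- function(x, sigmaVox, truncate = 4) {
  sigmaVox <- rep(sigmaVox, length.out = 3)
  for (ax in 1:3) {
    kern <- .gaussKernel(sigmaVox[ax], truncate)
    if (length(kern) > 1L) x <- .convolveAxis(x, kern, ax, pad = "reflect")
  }
  x
}
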