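test_that("normative model computes voxelwise mean and sample SD", {
  a <- randomDensity(seed = 1)
  b <- randomDensity(seed = 2)
  m <- buildNormative(list(a, b))
  # two-point sample SD = |difference| / sqrt(2)
  expect_equal(m@meanMap, (volData(a) + volData(b)) / 2)
  expect_equal(m@sdMap, abs(volData(a) - volData(b)) / sqrt(2))

  same <- buildNormative(list(a, a))
  expect_true(all(same@sdMap == 0))
  expect_equal(sum(same@validMask), 0)
})

test_that("normative mean/SD equal a per-voxel loop oracle", {
  maps <- lapply(1:10, function(s) randomDensity(d = c(4, 4, 4), seed = s))
  m <- buildNormative(maps)
  vals <- sapply(maps, volData)  # voxels x n
  for (v in sample(64, 10)) {
    expect_equal(m@meanMap[v], mean(vals[v, ]), tolerance = 1e-12)
    expect_equal(m@sdMap[v], sd(vals[v, ]), tolerance = 1e-12)
  }
})

test_that("degenerate normative inputs are rejected", {
  a <- randomDensity(seed = 1)
  expect_error(buildNormative(list(a)), "at least 2")
  b3 <- randomDensity(seed = 2, kernel = 3L)
  expect_error(buildNormative(list(a, b3)), "mixed kernel")
})

test_that("z-scoring standardizes against the control model", {
  maps <- lapply(1:6, function(s) randomDensity(seed = s))
  m <- buildNormative(maps)
  # subject identical to the mean map -> z = 0
  meanDens <- new("BoundaryDensityMap", data = m@meanMap,
                  voxelSize = voxelSize(maps[[1]]), spaceTag = spaceTag(maps[[1]]),
                  kernelSize = 5L)
  z0 <- zscoreMap(meanDens, m)
  expect_true(all(volData(z0) == 0))
  # subject one SD above the mean -> z = +1 on the valid mask
  up <- new("BoundaryDensityMap", data = pmin(m@meanMap + m@sdMap, 1),
            voxelSize = voxelSize(maps[[1]]), spaceTag = spaceTag(maps[[1]]),
            kernelSize = 5L)
  z1 <- zscoreMap(up, m)
  ok <- m@validMask & (m@meanMap + m@sdMap <= 1)
  expect_true(all(abs(volData(z1)[ok] - 1) < 1e-10))
  expect_true(all(volData(z1)[!validMask(z1)] == 0))

  bad <- new("BoundaryDensityMap", data = m@meanMap, voxelSize = voxelSize(maps[[1]]),
             spaceTag = spaceTag(maps[[1]]), kernelSize = 3L)
  expect_error(zscoreMap(bad, m), "kernel size mismatch")
})

test_that("a control cohort scored on its own model has mean 0 and SD 1", {
  maps <- lapply(1:8, function(s) randomDensity(d = c(5, 5, 5), seed = s + 100))
  m <- buildNormative(maps)
  zs <- zscoreCohort(maps, m)
  zmat <- sapply(zs, volData)
  v <- as.vector(m@validMask)
  mu <- rowMeans(zmat[v, ])
  sdv <- apply(zmat[v, ], 1, sd)
  expect_lt(max(abs(mu)), 1e-10)
  expect_lt(max(abs(sdv - 1)), 1e-10)
})

test_that("FWHM smoothing preserves constants and obeys the sigma identity", {
  expect_equal(fwhmToSigma(8), 8 / 2.3548200450309493, tolerance = 1e-12)
  v <- brainVolume(array(3.7, c(10, 10, 10)))
  s <- gaussianSmooth(v, fwhm = 8)
  expect_true(all(abs(volData(s) - 3.7) < 1e-12))
  expect_error(gaussianSmooth(brainVolume(array(NaN, c(4, 4, 4))), 8),
               "non-finite")
})

test_that("the delta response equals the explicit separable kernel", {
  d <- c(31, 31, 31)
  delta <- array(0, d); delta[16, 16, 16] <- 1
  fwhm <- 4
  got <- gaussianSmooth(delta, fwhm = fwhm, voxelSize = c(1, 1, 1))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  h <- ceiling(4 * sigma)
  g <- exp(-0.5 * ((-h:h) / sigma)^2); g <- g / sum(g)
  oracle <- array(0, d)
  for (i in -h:h) for (j in -h:h) for (l in -h:h)
    oracle[16 + i, 16 + j, 16 + l] <- g[i + h + 1] * g[j + h + 1] * g[l + h + 1]
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("smoothing is linear", {
  set.seed(3)
  x <- array(rnorm(8^3), c(8, 8, 8))
  y <- array(rnorm(8^3), c(8, 8, 8))
  lhs <- gaussianSmooth(2 * x - 3 * y, fwhm = 6, voxelSize = c(1, 1, 1))
  rhs <- 2 * gaussianSmooth(x, fwhm = 6, voxelSize = c(1, 1, 1)) -
    3 * gaussianSmooth(y, fwhm = 6, voxelSize = c(1, 1, 1))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("anisotropic voxels get per-axis sigma", {
  d <- c(21, 21, 11)
  delta <- array(0, d); delta[11, 11, 6] <- 1
  s <- gaussianSmooth(delta, fwhm = 8, voxelSize = c(1, 1, 2))
  # spread along z (2 mm voxels) decays faster in voxel units
  expect_gt(s[11 + 3, 11, 6], s[11, 11, 6 + 3])
})

test_that("severe boundary loss separates patients from controls", {
  spec <- studySpec()
  atlas <- makeToyAtlas(spec)
  shellZ <- function(cs, seed) {
    ph <- makePhantom(spec, diseaseSeverity(cs, 0.5, 0, 2), seed = seed)
    thr <- computeThresholds(ph$volume, ph$fractions)
    boxConvolve(computeGWBB(ph$volume, ph$fractions, thr), 5)
  }
  cn <- lapply(1:10, function(s) shellZ(1.0, s))
  ad <- lapply(1:10, function(s) shellZ(0.6, 100 + s))
  model <- buildNormative(cn)
  roiZ <- function(d) roiMeans(zscoreMap(d, model), atlas)$mean[1]
  cnZ <- vapply(cn, roiZ, numeric(1))
  adZ <- vapply(ad, roiZ, numeric(1))
  expect_true(all(adZ < median(cnZ)))
})
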