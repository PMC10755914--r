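# Build a 6-voxel volume where three voxels form the GM pool and three the
# WM pool, with hand-computable statistics.
poolFixture <- function(gmVals = c(90, 100, 110), wmVals = c(140, 150, 160)) {
  d <- c(3, 2, 1)
  t1 <- array(c(gmVals, wmVals), d)
  gm <- array(rep(c(0.6, 0), each = 3), d)
  wm <- array(rep(c(0, 0.6), each = 3), d)
  list(t1 = brainVolume(t1, spaceTag = "fix"),
       fr = tissueFractions(gm, wm, array(0, d), spaceTag = "fix"))
}

test_that("thresholds follow the half-2SD pool algebra", {
  fx <- poolFixture()
  thr <- computeThresholds(fx$t1, fx$fr)
  expect_equal(thr@gmMean, 100)
  expect_equal(thr@gmTwoSD, 20)   # sample SD 10
  expect_equal(thr@lower, 110)    # 100 + 20/2
  expect_equal(thr@wmMean, 150)
  expect_equal(thr@upper, 140)    # 150 - 20/2
  expect_false(thr@degenerate)
})

test_that("a zero-dispersion GM pool puts the lower threshold at its mean", {
  fx <- poolFixture(gmVals = c(100, 100, 100))
  thr <- computeThresholds(fx$t1, fx$fr)
  expect_equal(thr@lower, 100)
})

test_that("degenerate bands warn and give an empty gwBB map", {
  fx <- poolFixture(gmVals = c(140, 150, 160), wmVals = c(90, 100, 110))
  expect_warning(thr <- computeThresholds(fx$t1, fx$fr), "degenerate")
  expect_true(thr@degenerate)
  bb <- computeGWBB(fx$t1, fx$fr, thr)
  expect_true(all(volData(bb) == 0))
})

test_that("thresholds match the brute-force pool oracle on a phantom", {
  ph <- makePhantom(tinySpec(), diseaseSeverity(0.8, 0.4, 0, 2), seed = 21)
  thr <- computeThresholds(ph$volume, ph$fractions)
  orc <- oracleThresholds(volData(ph$volume),
                          tissueFraction(ph$fractions, "gm"),
                          tissueFraction(ph$fractions, "wm"))
  expect_equal(thr@lower, orc$lower, tolerance = 1e-12)
  expect_equal(thr@upper, orc$upper, tolerance = 1e-12)
})

test_that("gwBB applies the band rule only on GM/WM-dominant voxels", {
  d <- c(2, 2, 1)
  t1 <- brainVolume(array(c(120, 145, 120, 130), d), spaceTag = "fix")
  # voxel 3 has only 0.3 GM+WM tissue -> ineligible despite in-band intensity
  gm <- array(c(0.6, 0.6, 0.2, 0.3), d)
  wm <- array(c(0.3, 0.3, 0.1, 0.6), d)
  fr <- tissueFractions(gm, wm, array(0, d), spaceTag = "fix")
  thr <- new("ThresholdPair", lower = 110, upper = 140, gmMean = 100,
             gmTwoSD = 20, wmMean = 150, wmTwoSD = 20, degenerate = FALSE)
  bb <- computeGWBB(t1, fr, thr)
  expect_equal(as.vector(volData(bb)), c(1, 0, 0, 1))
})

test_that("the gwBB fraction shrinks as gray-white contrast collapses", {
  spec <- studySpec()
  frac <- vapply(c(1.0, 0.6, 0.3), function(cs) {
    ph <- makePhantom(spec, diseaseSeverity(cs, 0.5, 0, 2), seed = 11)
    thr <- computeThresholds(ph$volume, ph$fractions)
    bb <- computeGWBB(ph$volume, ph$fractions, thr)
    sum(volData(bb)) / sum(validMask(bb))
  }, numeric(1))
  expect_true(all(diff(frac) < 0))
})

test_that("box convolution handles degenerate and closed-form cases", {
  z <- boxConvolve(array(0, c(7, 7, 7)), 5)
  expect_true(all(volData(z) == 0))

  o <- boxConvolve(array(1, c(7, 7, 7)), 5)
  expect_equal(volData(o)[4, 4, 4], 1)          # interior
  expect_equal(volData(o)[1, 1, 1], 27 / 125)   # corner
  expect_equal(volData(o)[4, 4, 1], 75 / 125)   # face centre

  delta <- array(0, c(9, 9, 9)); delta[5, 5, 5] <- 1
  dm <- volData(boxConvolve(delta, 5))
  idx <- which(dm > 0, arr.ind = TRUE)
  cheb <- apply(abs(idx - 5), 1, max)
  expect_true(all(cheb <= 2))
  expect_equal(sum(dm > 0), 125)
  expect_true(all(abs(dm[dm > 0] - 1 / 125) < 1e-15))
})

test_that("kernel size 1 is the identity and even kernels are rejected", {
  set.seed(2)
  x <- array(rbinom(4^3, 1, 0.5), c(4, 4, 4))
  expect_equal(volData(boxConvolve(x, 1)), x + 0)
  expect_error(boxConvolve(x, 4), "odd")
})

test_that("box convolution equals the triple-loop oracle and conserves mass", {
  set.seed(7)
  for (rep in 1:3) {
    d <- sample(6:10, 3, replace = TRUE)
    x <- array(rbinom(prod(d), 1, 0.25), d)
    for (k in c(1L, 3L, 5L)) {
      got <- volData(boxConvolve(x, k))
      expect_equal(got, oracleBoxConvolve(x, k), tolerance = 1e-12)
      # mass is conserved when the support keeps a half-kernel margin from
      # the grid edge (always true for brain maps with background border)
      h <- (k - 1L) / 2L
      xi <- array(0, d)
      xi[(1 + h):(d[1] - h), (1 + h):(d[2] - h), (1 + h):(d[3] - h)] <-
        x[(1 + h):(d[1] - h), (1 + h):(d[2] - h), (1 + h):(d[3] - h)]
      goti <- volData(boxConvolve(xi, k))
      expect_lt(abs(sum(goti) - sum(xi)) / max(sum(xi), 1), 1e-9)
    }
  }
})
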