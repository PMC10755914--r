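test_that("ROI means equal a per-label loop oracle", {
  d <- c(6, 6, 6)
  set.seed(4)
  labs <- array(sample(0:3, prod(d), replace = TRUE), d)
  atlas <- roiAtlas(labs, c("1" = "a", "2" = "b", "3" = "c"))
  x <- array(rnorm(prod(d)), d)
  rm <- roiMeans(x, atlas)
  for (l in 1:3)
    expect_equal(rm$mean[rm$label == l], mean(x[labs == l]), tolerance = 1e-12)

  const <- array(0.3, d)
  expect_true(all(abs(roiMeans(const, atlas)$mean - 0.3) < 1e-15))

  two <- array(0L, d); two[1] <- 1L; two[2] <- 1L
  a2 <- roiAtlas(two, c("1" = "pair"))
  y <- array(0, d); y[1] <- -1; y[2] <- 1
  expect_equal(roiMeans(y, a2)$mean, 0)
})

test_that("ANCOVA group F equals the RSS-ratio oracle on a small dataset", {
  set.seed(10)
  n <- 9
  g <- factor(rep(c("CN", "MCI", "AD"), each = 3), levels = c("CN", "MCI", "AD"))
  covm <- cbind(age = rnorm(n, 72, 5), tiv = rnorm(n, 1350, 100))
  y <- rnorm(n) + as.integer(g) * 0.5 + 0.01 * covm[, "age"]
  av <- ancovaGroup(y, g, as.data.frame(covm))
  orc <- oracleAncovaF(y, g, covm)
  expect_equal(av$F, orc$F, tolerance = 1e-10)
  expect_equal(av$df1, orc$df1)
  expect_equal(av$df2, orc$df2)
  expect_equal(av$p, pf(orc$F, orc$df1, orc$df2, lower.tail = FALSE),
               tolerance = 1e-10)
  # with 3 groups and 2 covariates, df = (2, n-5)
  expect_equal(c(av$df1, av$df2), c(2, n - 5))
})

test_that("ANCOVA post-hoc is Bonferroni-capped and F is covariate-scale invariant", {
  set.seed(11)
  n <- 30
  g <- factor(rep(c("CN", "MCI", "AD"), each = 10))
  covs <- data.frame(age = rnorm(n, 72, 5), tiv = rnorm(n, 1350, 100))
  y <- rnorm(n) + (g == "AD") * 1.5
  av <- ancovaGroup(y, g, covs)
  expect_true(all(av$posthoc$p_bonf <= 1))
  expect_equal(av$posthoc$p_bonf, pmin(1, 3 * av$posthoc$p_raw))
  # affine rescaling of covariates leaves F untouched
  covs2 <- data.frame(age = 100 * covs$age - 7, tiv = covs$tiv / 1000 + 2)
  expect_equal(ancovaGroup(y, g, covs2)$F, av$F, tolerance = 1e-9)
  expect_error(ancovaGroup(y, g, data.frame(a = covs$age, b = covs$age)),
               "rank deficient")
  expect_error(ancovaGroup(y[1:11], droplevels(g[1:11]), covs[1:11, ]),
               "at least 2")
})

test_that("partial correlation generalizes Pearson and respects signs", {
  set.seed(12)
  x <- rnorm(50); y <- 0.5 * x + rnorm(50)
  pc <- partialCorr(x, y, NULL)
  pe <- pearsonCorr(x, y)
  expect_equal(pc$r, pe$r, tolerance = 1e-12)
  expect_equal(pc$p, pe$p, tolerance = 1e-12)
  expect_equal(pc$df, pe$df)

  # y = x + age with x independent of age: adjusting recovers the x signal
  n <- 200
  age <- rnorm(n, 72, 5)
  x2 <- rnorm(n)
  y2 <- x2 + age
  pr <- partialCorr(x2, y2, data.frame(age = age))
  expect_gt(pr$r, 0.95)
  expect_equal(pr$df, n - 3)

  # exact negative linearity after orthogonal covariates
  z <- rnorm(50)
  pn <- partialCorr(x, -x, data.frame(z = z))
  expect_equal(pn$r, -1, tolerance = 1e-12)

  pfl <- partialCorr(x, rep(1, 50), NULL)
  expect_true(is.na(pfl$r))
  expect_equal(pfl$flag, "constant residuals")
})

test_that("Pearson correlation matches the closed-form on a 4-point set", {
  x <- c(1, 2, 4, 8); y <- c(2, 1, 5, 6)
  ct <- pearsonCorr(x, y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ct$r, r, tolerance = 1e-12)
  expect_equal(pearsonCorr(x, 2 * x + 1)$r, 1)
  set.seed(13)
  xs <- rnorm(1000)
  expect_lt(abs(pearsonCorr(xs, sample(xs))$r), 0.1)
  expect_error(pearsonCorr(x, rep(1, 4)), "constant")
})

test_that("BH-FDR equals the exhaustive step-up scan", {
  set.seed(14)
  p <- runif(50)^2
  res <- bhFdr(p, 0.05)
  expect_identical(res$reject, oracleBH(p, 0.05))
  # adjusted p-values threshold consistently
  expect_identical(res$reject, res$adjusted <= 0.05)
  # alpha = 0.01 rejections are a subset of alpha = 0.05
  r01 <- bhFdr(p, 0.01)$reject
  expect_true(all(!r01 | res$reject))

  expect_true(all(bhFdr(rep(0, 5), 0.01)$reject))
  expect_equal(bhFdr(0.03, 0.05)$adjusted, 0.03)
  expect_error(bhFdr(c(0.1, 1.2)), "out of")
})
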