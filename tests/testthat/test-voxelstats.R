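test_that("voxelwise GLM statistics equal their scalar oracles per voxel", {
  set.seed(20)
  n <- 24
  d <- c(3, 3, 3)
  g <- factor(rep(c("CN", "MCI", "AD"), each = 8))
  covs <- data.frame(age = rnorm(n, 72, 5), tiv = rnorm(n, 1350, 100))
  maps <- lapply(1:n, function(i) array(rnorm(prod(d)), d) +
                   (g[i] == "AD") * 0.8)
  fitF <- voxelGLM(maps, groups = g, covariates = covs)
  vals <- sapply(maps, function(m) m[2, 2, 2])
  av <- ancovaGroup(vals, g, covs)
  expect_equal(fitF$stat[2, 2, 2], av$F, tolerance = 1e-10)
  expect_equal(fitF$p[2, 2, 2], av$p, tolerance = 1e-10)

  fitT <- voxelGLM(maps, covariates = covs, slopeTerm = "age")
  lmfit <- summary(lm(vals ~ age + tiv, data = covs))
  expect_equal(fitT$stat[2, 2, 2], lmfit$coefficients["age", "t value"],
               tolerance = 1e-10)
  expect_equal(fitT$p[2, 2, 2], lmfit$coefficients["age", "Pr(>|t|)"],
               tolerance = 1e-10)
})

test_that("null data give a uniform voxelwise p-value distribution", {
  set.seed(21)
  n <- 30
  d <- c(10, 10, 5)  # 500 voxels
  g <- factor(rep(c("A", "B", "C"), each = 10))
  covs <- data.frame(age = rnorm(n), tiv = rnorm(n))
  maps <- lapply(1:n, function(i) array(rnorm(prod(d)), d))
  fit <- voxelGLM(maps, groups = g, covariates = covs)
  ks <- ks.test(as.vector(fit$p), "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("cluster extent rule keeps 100-voxel blobs and drops 99-voxel ones", {
  d <- c(20, 20, 20)
  mask <- array(FALSE, d)
  mask[1:5, 1:5, 1:4] <- TRUE                # 100 voxels
  blob2 <- array(FALSE, d); blob2[10:18, 10:12, 15:18] <- TRUE  # 108
  mask2 <- mask | blob2
  mask2[3, 3, 2] <- mask2[3, 3, 2]           # keep as is
  res <- clusterThreshold(mask2, minExtent = 100, connectivity = 18)
  expect_equal(nrow(res$table), 2)
  expect_equal(sort(res$table$size), c(100, 108))

  small <- array(FALSE, d); small[1:11, 1:3, 1:3] <- TRUE  # 99 voxels
  expect_equal(sum(small), 99)
  res99 <- clusterThreshold(small, minExtent = 100, connectivity = 18)
  expect_equal(nrow(res99$table), 0)
  expect_true(all(!res$mask[!mask2]))
})

test_that("corner-only contact splits under 18- but not 26-connectivity", {
  m <- array(FALSE, c(4, 4, 4))
  m[2, 2, 2] <- TRUE
  m[3, 3, 3] <- TRUE  # shares only a corner
  r18 <- clusterThreshold(m, minExtent = 1, connectivity = 18)
  r26 <- clusterThreshold(m, minExtent = 1, connectivity = 26)
  expect_equal(nrow(r18$table), 2)
  expect_equal(nrow(r26$table), 1)
  # face contact joins under 6-connectivity
  m2 <- array(FALSE, c(4, 4, 4)); m2[2, 2, 2] <- TRUE; m2[2, 2, 3] <- TRUE
  expect_equal(nrow(clusterThreshold(m2, 1, 6)$table), 1)
})

test_that("component labeling matches the min-propagation oracle", {
  set.seed(22)
  for (conn in c(6L, 18L, 26L)) {
    mask <- array(runif(8^3) < 0.2, c(8, 8, 8))
    res <- clusterThreshold(mask, minExtent = 1, connectivity = conn)
    orc <- oracleLabelComponents(mask, conn)
    expect_true(samePartition(res$labels, orc))
  }
})
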