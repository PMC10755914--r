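test_that("pure WM voxels have exact WM intensity and unit fraction", {
  spec <- tinySpec(supersample = 3L)
  ph <- makePhantom(spec, diseaseSeverity(contrastScale = 1, boundaryBlur = 0,
                                          atrophy = 0, noiseSD = 0), seed = 1)
  fWM <- tissueFraction(ph$fractions, "wm")
  core <- fWM == 1
  expect_gt(sum(core), 0)
  expect_true(all(volData(ph$volume)[core] == spec$intensities[["wm"]]))
})

test_that("contrast collapse rescales only the GM intensity term", {
  spec <- tinySpec()
  a <- makePhantom(spec, diseaseSeverity(1.0, 0, 0, 2), seed = 5)
  b <- makePhantom(spec, diseaseSeverity(0.5, 0, 0, 2), seed = 5)
  diff <- volData(a$volume) - volData(b$volume)  # same seed: noise cancels
  fGM <- tissueFraction(a$fractions, "gm")
  expect_true(all(abs(diff[fGM == 0]) < 1e-12))
  expect_true(all(abs(diff[fGM > 0]) > 0))
})

test_that("supersampled WM fraction reproduces the analytic sphere volume", {
  spec <- phantomSpec(supersample = 5L)  # 40^3, 1 mm, WM radius 12
  ph <- makePhantom(spec, diseaseSeverity(), seed = 1)
  est <- sum(tissueFraction(ph$fractions, "wm")) * voxelVolume(ph$fractions)
  expect_lt(abs(est - 4 / 3 * pi * 12^3) / (4 / 3 * pi * 12^3), 0.01)
})

test_that("fractions are proper partial volumes", {
  ph <- makePhantom(tinySpec(), diseaseSeverity(0.7, 0.5, 0.5, 3), seed = 2)
  f <- ph$fractions
  tot <- tissueFraction(f, "gm") + tissueFraction(f, "wm") + tissueFraction(f, "csf")
  expect_true(all(tot >= -1e-9 & tot <= 1 + 1e-9))
  # fully inside / fully outside voxels sum to exactly 1 / 0
  expect_true(any(tot > 1 - 1e-9))
  expect_true(any(tot == 0))
  for (t in c("gm", "wm", "csf")) {
    fr <- tissueFraction(f, t)
    expect_true(all(fr >= -1e-9 & fr <= 1 + 1e-9))
  }
})

test_that("WM volume error decreases with supersampling", {
  truth <- 4 / 3 * pi * 3^3
  err <- vapply(c(1L, 3L, 5L), function(s) {
    ph <- makePhantom(tinySpec(supersample = s), diseaseSeverity(), seed = 1)
    abs(sum(tissueFraction(ph$fractions, "wm")) - truth)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("atrophy eliminating the GM shell is an error", {
  expect_error(makePhantom(tinySpec(), diseaseSeverity(1, 0, 2, 0), seed = 1),
               "GM shell eliminated")
})

test_that("cohort generation is deterministic under a fixed seed", {
  spec <- tinySpec()
  cs <- cohortSpec(nPerGroup = c(CN = 3, MCI = 3, AD = 3), seed = 9)
  a <- makeCohort(cs, spec)
  b <- makeCohort(cs, spec)
  expect_identical(a$table, b$table)
  expect_identical(lapply(a$subjects, function(s) volData(s$volume)),
                   lapply(b$subjects, function(s) volData(s$volume)))
})

test_that("K-MMSE declines with planted contrast loss; CDR is fixed per group", {
  cs <- cohortSpec(nPerGroup = c(CN = 20, MCI = 20, AD = 20), seed = 4)
  man <- makeCohort(cs, tinySpec(), keepVolumes = FALSE)
  tab <- man$table
  expect_gte(nrow(tab), 60)
  expect_lt(cor(1 - tab$contrast_scale, tab$kmmse), 0)
  expect_true(all(tab$kmmse >= 0 & tab$kmmse <= 30))
  expect_true(all(tab$cdr[tab$group == "CN"] == 0))
  expect_true(all(tab$cdr[tab$group == "MCI"] == 0.5))
  expect_true(all(tab$cdr[tab$group == "AD"] == 1))
  expect_false(anyDuplicated(tab$subject_id) > 0)
})

test_that("toy atlas has three disjoint nonempty ROIs around the interface", {
  spec <- studySpec()
  atlas <- makeToyAtlas(spec)
  labs <- volData(atlas)
  expect_setequal(unique(as.vector(labs)), c(0L, 1L, 2L, 3L))
  expect_true(all(tabulate(labs[labs > 0]) > 0))
  # interface voxels at radius = WM semi-axis along an axis are boundary shell
  ctr <- spec$gridShape[1] / 2  # mm; voxel i covers (i-1, i]
  for (r in c(-12, 12)) {
    i <- ceiling(ctr + r)
    expect_equal(labs[i, 20, 20], 1L)
  }
  # WM core centre voxel
  expect_equal(labs[20, 20, 20], 3L)
})
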