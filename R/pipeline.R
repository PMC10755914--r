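#' Pipeline configuration
#'
#' Bundles the analysis settings with their standard defaults: 5x5x5 box
#' kernel, 8 mm FWHM smoothing, voxelwise BH-FDR at alpha 0.01 with
#' 100-voxel cluster extent under 18-connectivity, normative SD floor 1e-6.
#' All randomness is funneled through the single root `seed` (it overrides
#' the cohort spec's own seed). A resolved copy of the configuration is
#' written next to the outputs on every run.
#'
#' @param outputDir output directory for all artifacts.
#' @param phantom a [phantomSpec()].
#' @param cohort a [cohortSpec()].
#' @param kernelSize box kernel edge (odd, default 5).
#' @param fwhm smoothing FWHM in mm (default 8).
#' @param fdrAlpha voxelwise FDR level (default 0.01).
#' @param minExtent minimum cluster extent in voxels (default 100).
#' @param connectivity cluster connectivity, 6/18/26 (default 18).
#' @param sdFloor normative SD floor (default 1e-6).
#' @param seed root RNG seed.
#' @param stages character vector of stages to run, in order, from
#'   `simulate`, `boundary`, `normative`, `zmap`, `roiStats`, `voxelStats`,
#'   `classify`.
#' @param segmentation `"passthrough"` (use the fraction volumes on disk /
#'   the generator's ground truth) or `"gmm"` (re-estimate fractions with
#'   [segmentGMM()]).
#' @param loo score controls against leave-one-out normative models.
#' @param classifierRoi ROI name used for the classification stage.
#' @return A `PipelineConfig` (list).
#' @export
pipelineConfig <- function(outputDir,
                           phantom = phantomSpec(),
                           cohort = cohortSpec(),
                           kernelSize = 5L, fwhm = 8, fdrAlpha = 0.01,
                           minExtent = 100L, connectivity = 18L,
                           sdFloor = 1e-6, seed = 1L,
                           stages = c("simulate", "boundary", "normative",
                                      "zmap", "roiStats", "voxelStats",
                                      "classify"),
                           segmentation = c("passthrough", "gmm"),
                           loo = FALSE,
                           classifierRoi = "boundary_shell") {
  segmentation <- match.arg(segmentation)
  known <- c("simulate", "boundary", "normative", "zmap", "roiStats",
             "voxelStats", "classify")
  stopifnot(all(stages %in% known), kernelSize %% 2L == 1L, fwhm > 0,
            fdrAlpha > 0, fdrAlpha < 1, minExtent >= 1,
            connectivity %in% c(6L, 18L, 26L))
  structure(list(outputDir = outputDir, phantom = phantom, cohort = cohort,
                 kernelSize = as.integer(kernelSize), fwhm = fwhm,
                 fdrAlpha = fdrAlpha, minExtent = as.integer(minExtent),
                 connectivity = as.integer(connectivity), sdFloor = sdFloor,
                 seed = as.integer(seed), stages = stages,
                 segmentation = segmentation, loo = loo,
                 classifierRoi = classifierRoi),
            class = "PipelineConfig")
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full boundary-mapping pipeline
#'
#' Executes the enabled stages in order: simulate (phantom cohort + toy
#' atlas), boundary (per-subject thresholds, gwBB, box-convolved gwBTV map),
#' normative (control mean/SD maps), zmap (gwBZ maps; 8 mm FWHM smoothing of
#' gwBZ and gwBTV), roiStats (ROI table, group ANCOVA with age and TIV as
#' covariates with Bonferroni post-hoc, Pearson correlation with age,
#' partial correlation with K-MMSE adjusted by age and TIV), voxelStats
#' (voxelwise ANCOVA with BH-FDR and cluster-extent filtering) and classify
#' (pairwise logistic/ROC biomarker combinations in the classifier ROI).
#' Reruns under the same configuration are bit-identical; a manifest of all
#' artifacts with checksums and a resolved config copy are written to the
#' output directory.
#'
#' @param config a [pipelineConfig()].
#' @param quiet suppress progress messages.
#' @return list: `table` (cohort), `thresholds`, `model`, `roiTable`,
#'   `groupAncova`, `correlations`, `classification`, `clusters`,
#'   `manifestFile`.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$outputDir
  volDir <- file.path(out, "volumes")
  mapDir <- file.path(out, "maps")
  modelDir <- file.path(out, "model")
  statDir <- file.path(out, "stats")
  for (d in c(out, volDir, mapDir, modelDir, statDir))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stages <- config$stages
  spec <- config$phantom
  cohort <- config$cohort
  cohort$seed <- config$seed

  # --- simulate ---------------------------------------------------------
  if ("simulate" %in% stages) {
    say("simulate: %d subjects on a %s grid",
        sum(cohort$nPerGroup), paste(spec$gridShape, collapse = "x"))
    manifest <- makeCohort(cohort, spec, dir = volDir, keepVolumes = FALSE)
    # rewrite the CSV with paths relative to the output dir so that reruns
    # into different directories are checksum-comparable
    relTab <- manifest$table
    for (col in grep("_path$", names(relTab), value = TRUE))
      relTab[[col]] <- basename(relTab[[col]])
    utils::write.csv(relTab, file.path(volDir, "cohort.csv"), row.names = FALSE)
  } else {
    csv <- file.path(volDir, "cohort.csv")
    if (!file.exists(csv))
      stop("missing upstream artifact for disabled 'simulate' stage: ", csv)
    tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
    for (col in grep("_path$", names(tab), value = TRUE))
      tab[[col]] <- file.path(volDir, tab[[col]])
    atlas <- readAtlas(file.path(volDir, "atlas.nii.gz"),
                       nameMap = c("1" = "boundary_shell", "2" = "gm_shell",
                                   "3" = "wm_core"),
                       spaceTag = spec$spaceTag)
    manifest <- structure(list(table = tab, subjects = NULL, atlas = atlas,
                               spec = spec, cohortSpec = cohort, dir = volDir),
                          class = "CohortManifest")
  }
  tab <- manifest$table
  n <- nrow(tab)
  ids <- tab$subject_id
  groups <- factor(tab$group, levels = names(cohort$nPerGroup))

  # --- boundary ---------------------------------------------------------
  densities <- NULL
  thresholds <- NULL
  if ("boundary" %in% stages) {
    say("boundary: thresholds + gwBB + %dx%dx%d box convolution",
        config$kernelSize, config$kernelSize, config$kernelSize)
    densities <- vector("list", n)
    names(densities) <- ids
    thr <- data.frame(subject_id = ids, lower = NA_real_, upper = NA_real_,
                      gm_mean = NA_real_, gm_2sd = NA_real_,
                      wm_mean = NA_real_, wm_2sd = NA_real_,
                      degenerate = FALSE)
    for (i in seq_len(n)) {
      sub <- .cohortSubject(manifest, i)
      fr <- sub$fractions
      if (config$segmentation == "gmm")
        fr <- segmentGMM(sub$volume, mask = brainMask(fr))$fractions
      tp <- computeThresholds(sub$volume, fr)
      bb <- computeGWBB(sub$volume, fr, tp)
      densities[[i]] <- boxConvolve(bb, config$kernelSize)
      writeVolume(brainVolume(volData(densities[[i]]), spec$voxelSize,
                              spec$spaceTag),
                  file.path(mapDir, paste0(ids[i], "_gwbtv.nii.gz")))
      thr[i, 2:7] <- c(tp@lower, tp@upper, tp@gmMean, tp@gmTwoSD,
                       tp@wmMean, tp@wmTwoSD)
      thr$degenerate[i] <- tp@degenerate
    }
    thresholds <- thr
    utils::write.csv(thr, file.path(statDir, "thresholds.csv"), row.names = FALSE)
  }

  loadDensity <- function(id) {
    f <- file.path(mapDir, paste0(id, "_gwbtv.nii.gz"))
    if (!file.exists(f)) stop("missing gwBTV map for subject ", id, ": ", f)
    v <- readVolume(f, spec$spaceTag)
    new("BoundaryDensityMap", data = volData(v), voxelSize = voxelSize(v),
        spaceTag = spaceTag(v), kernelSize = config$kernelSize)
  }
  if (is.null(densities) &&
      any(c("normative", "zmap", "roiStats", "voxelStats", "classify") %in% stages))
    densities <- stats::setNames(lapply(ids, loadDensity), ids)

  # --- normative --------------------------------------------------------
  model <- NULL
  cnLevel <- levels(groups)[1]
  if ("normative" %in% stages) {
    cnIdx <- which(groups == cnLevel)
    say("normative: %d %s controls", length(cnIdx), cnLevel)
    model <- buildNormative(densities[cnIdx], sdFloor = config$sdFloor)
    writeVolume(brainVolume(model@meanMap, spec$voxelSize, spec$spaceTag),
                file.path(modelDir, "mean.nii.gz"))
    writeVolume(brainVolume(model@sdMap, spec$voxelSize, spec$spaceTag),
                file.path(modelDir, "sd.nii.gz"))
    .writeJson(list(n_controls = model@nControls, kernel_size = model@kernelSize,
                    sd_floor = model@sdFloor, control_group = cnLevel),
               file.path(modelDir, "meta.json"))
  } else if (any(c("zmap", "roiStats", "voxelStats", "classify") %in% stages)) {
    mf <- file.path(modelDir, "mean.nii.gz")
    sf <- file.path(modelDir, "sd.nii.gz")
    if (!file.exists(mf) || !file.exists(sf))
      stop("missing normative model (run the 'normative' stage first): ", mf)
    meta <- jsonlite::read_json(file.path(modelDir, "meta.json"))
    sdMap <- volData(readVolume(sf, spec$spaceTag))
    model <- new("NormativeModel",
                 meanMap = volData(readVolume(mf, spec$spaceTag)),
                 sdMap = sdMap, nControls = as.integer(meta$n_controls),
                 validMask = sdMap > meta$sd_floor, sdFloor = meta$sd_floor,
                 kernelSize = as.integer(meta$kernel_size),
                 voxelSize = spec$voxelSize, spaceTag = spec$spaceTag)
  }

  # --- zmap -------------------------------------------------------------
  zs <- dens_s <- NULL
  if ("zmap" %in% stages) {
    say("zmap: gwBZ + %g mm FWHM smoothing", config$fwhm)
    cnIdx <- which(groups == cnLevel)
    zmaps <- vector("list", n)
    for (i in seq_len(n)) {
      zmaps[[i]] <- if (config$loo && i %in% cnIdx)
        zscoreCohort(densities[i], model, loo = TRUE,
                     controls = densities[cnIdx][-match(i, cnIdx)])[[1]]
      else zscoreMap(densities[[i]], model)
    }
    zs <- lapply(zmaps, gaussianSmooth, fwhm = config$fwhm)
    dens_s <- lapply(densities, function(d)
      gaussianSmooth(brainVolume(volData(d), voxelSize(d), spaceTag(d)),
                     fwhm = config$fwhm))
    for (i in seq_len(n)) {
      writeVolume(zs[[i]], file.path(mapDir, paste0(ids[i], "_gwbz_s.nii.gz")))
      writeVolume(dens_s[[i]], file.path(mapDir, paste0(ids[i], "_gwbtv_s.nii.gz")))
    }
  } else if (any(c("roiStats", "voxelStats", "classify") %in% stages)) {
    loadMap <- function(id, suffix) {
      f <- file.path(mapDir, paste0(id, "_", suffix, ".nii.gz"))
      if (!file.exists(f)) stop("missing smoothed map (run 'zmap' first): ", f)
      readVolume(f, spec$spaceTag)
    }
    zs <- lapply(ids, loadMap, suffix = "gwbz_s")
    dens_s <- lapply(ids, loadMap, suffix = "gwbtv_s")
  }

  # --- roiStats ---------------------------------------------------------
  roiTable <- groupAncova <- correlations <- NULL
  atlas <- manifest$atlas
  covs <- data.frame(age = tab$age, tiv = tab$tiv_cm3)
  if ("roiStats" %in% stages) {
    say("roiStats: ROI means + ANCOVA + correlations")
    rows <- list()
    for (i in seq_len(n)) {
      for (mt in c("gwBZ", "gwBTV")) {
        rm <- roiMeans(if (mt == "gwBZ") zs[[i]] else dens_s[[i]], atlas)
        rows[[length(rows) + 1]] <- data.frame(subject_id = ids[i], map = mt,
                                               roi = rm$roi, value = rm$mean)
      }
    }
    roiTable <- do.call(rbind, rows)
    roiTable <- merge(roiTable,
                      tab[, c("subject_id", "group", "age", "kmmse", "cdr",
                              "tiv_cm3")],
                      by = "subject_id", sort = FALSE)
    utils::write.csv(roiTable, file.path(statDir, "roi_values.csv"),
                     row.names = FALSE)

    gaRows <- corRows <- list()
    for (mt in c("gwBZ", "gwBTV")) for (r in unique(roiTable$roi)) {
      sel <- roiTable$map == mt & roiTable$roi == r
      sub <- roiTable[sel, ]
      sub <- sub[match(ids, sub$subject_id), ]
      av <- ancovaGroup(sub$value, groups, covs)
      gm <- tapply(sub$value, groups, mean)
      gsd <- tapply(sub$value, groups, stats::sd)
      row <- data.frame(map = mt, roi = r, F = av$F, p = av$p)
      for (g in levels(groups)) {
        row[[paste0("mean_", g)]] <- gm[[g]]
        row[[paste0("sd_", g)]] <- gsd[[g]]
      }
      for (j in seq_len(nrow(av$posthoc)))
        row[[paste0("p_", gsub("-", "_", av$posthoc$pair[j]))]] <- av$posthoc$p_bonf[j]
      gaRows[[length(gaRows) + 1]] <- row

      pc <- pearsonCorr(sub$value, tab$age)
      kc <- partialCorr(sub$value, tab$kmmse, covs)
      corRows[[length(corRows) + 1]] <- data.frame(
        map = mt, roi = r, r_age = pc$r, p_age = pc$p,
        r_kmmse = kc$r, p_kmmse = kc$p)
    }
    groupAncova <- do.call(rbind, gaRows)
    correlations <- do.call(rbind, corRows)
    utils::write.csv(groupAncova, file.path(statDir, "group_ancova.csv"),
                     row.names = FALSE)
    utils::write.csv(correlations, file.path(statDir, "correlations.csv"),
                     row.names = FALSE)
  }

  # --- voxelStats -------------------------------------------------------
  clusters <- NULL
  if ("voxelStats" %in% stages) {
    say("voxelStats: voxelwise ANCOVA, FDR %.3g, extent %d, connectivity %d",
        config$fdrAlpha, config$minExtent, config$connectivity)
    clusters <- list()
    for (mt in c("gwBZ", "gwBTV")) {
      mapsList <- if (mt == "gwBZ") zs else dens_s
      fit <- voxelGLM(mapsList, mask = model@validMask, groups = groups,
                      covariates = covs)
      res <- significantClusters(fit, alpha = config$fdrAlpha,
                                 minExtent = config$minExtent,
                                 connectivity = config$connectivity)
      writeVolume(brainVolume(fit$stat, spec$voxelSize, spec$spaceTag),
                  file.path(statDir, paste0("F_", mt, ".nii.gz")))
      writeVolume(brainVolume(res$labels + 0L, spec$voxelSize, spec$spaceTag),
                  file.path(statDir, paste0("clusters_", mt, ".nii.gz")))
      utils::write.csv(res$table,
                       file.path(statDir, paste0("clusters_", mt, ".csv")),
                       row.names = FALSE)
      clusters[[mt]] <- res
    }
  }

  # --- classify ---------------------------------------------------------
  classification <- NULL
  if ("classify" %in% stages) {
    say("classify: logistic + ROC in ROI '%s'", config$classifierRoi)
    if (is.null(roiTable)) stop("classify requires the 'roiStats' stage")
    wide <- roiTable[roiTable$roi == config$classifierRoi, ]
    gwbz <- wide$value[wide$map == "gwBZ"][match(ids, wide$subject_id[wide$map == "gwBZ"])]
    gwbtv <- wide$value[wide$map == "gwBTV"][match(ids, wide$subject_id[wide$map == "gwBTV"])]
    featSets <- list(
      "gwBZ" = data.frame(gwbz = gwbz),
      "gwBTV" = data.frame(gwbtv = gwbtv),
      "gwBZ & gwBTV" = data.frame(gwbz = gwbz, gwbtv = gwbtv),
      "gwBZ & K-MMSE" = data.frame(gwbz = gwbz, kmmse = tab$kmmse),
      "gwBTV & K-MMSE" = data.frame(gwbtv = gwbtv, kmmse = tab$kmmse),
      "gwBZ & CDR" = data.frame(gwbz = gwbz, cdr = tab$cdr),
      "gwBTV & CDR" = data.frame(gwbtv = gwbtv, cdr = tab$cdr),
      "gwBZ & gwBTV & K-MMSE" = data.frame(gwbz = gwbz, gwbtv = gwbtv,
                                           kmmse = tab$kmmse))
    lv <- levels(groups)
    pairs <- utils::combn(lv, 2, simplify = FALSE)
    rows <- list()
    for (fs in names(featSets)) for (pr in pairs) {
      sel <- groups %in% pr
      res <- logisticRoc(featSets[[fs]][sel, , drop = FALSE],
                         factor(as.character(groups[sel]), levels = pr),
                         positive = pr[2])
      rows[[length(rows) + 1]] <- data.frame(
        features = fs, pair = paste(pr, collapse = " vs "),
        SE = res$sensitivity, SP = res$specificity, AUC = res$auc, p = res$p,
        separation = res$separation)
    }
    classification <- do.call(rbind, rows)
    utils::write.csv(classification, file.path(statDir, "classification.csv"),
                     row.names = FALSE)
  }

  # --- manifest ---------------------------------------------------------
  cfgOut <- unclass(config)
  cfgOut$outputDir <- NULL
  cfgOut$phantom <- unclass(cfgOut$phantom)
  cfgOut$cohort <- unclass(cfgOut$cohort)
  .writeJson(cfgOut, file.path(out, "config.json"))
  files <- sort(list.files(out, recursive = TRUE))
  files <- setdiff(files, "manifest.json")
  sums <- unname(tools::md5sum(file.path(out, files)))
  .writeJson(list(files = data.frame(path = files, md5 = sums)),
             file.path(out, "manifest.json"))

  invisible(list(table = tab, thresholds = thresholds, model = model,
                 roiTable = roiTable, groupAncova = groupAncova,
                 correlations = correlations, classification = classification,
                 clusters = clusters,
                 manifestFile = file.path(out, "manifest.json")))
}
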