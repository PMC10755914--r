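#' Per-ROI mean values of a map
#'
#' @param map a [BrainVolume-class] (or subclass) or 3D array.
#' @param atlas an [ROIAtlas-class] in the same space.
#' @return data.frame with columns `label`, `roi`, `mean`, `nVoxels`. An ROI
#'   with zero voxels gets `mean = NA` (flagged missing).
#' @export
roiMeans <- function(map, atlas) {
  stopifnot(is(atlas, "ROIAtlas"))
  data <- if (is(map, "BrainVolume")) { checkCommonSpace(list(map, atlas)); volData(map) } else map
  stopifnot(identical(dim(data), dim(atlas@labels)))
  labs <- as.integer(names(atlas@nameMap))
  res <- lapply(labs, function(l) {
    sel <- atlas@labels == l
    nv <- sum(sel)
    data.frame(label = l, roi = unname(atlas@nameMap[as.character(l)]),
               mean = if (nv > 0) mean(data[sel]) else NA_real_,
               nVoxels = nv)
  })
  do.call(rbind, res)
}

.covariateMatrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(nrow = n, ncol = 0))
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == n)
  m <- as.matrix(covariates)
  storage.mode(m) <- "double"
  m
}

#' Group ANCOVA with covariates and Bonferroni post-hoc
#'
#' Fits the linear model `y ~ group + covariates` and reports the partial F
#' test of the group factor (the covariate-adjusted group comparison; with 3
#' groups and 2 covariates, df = (2, n - 5)). Post-hoc pairwise group
#' contrasts are taken from the full model and Bonferroni-adjusted
#' (`p_adj = min(1, 3 * p_raw)` for 3 groups).
#'
#' @param values numeric response (e.g. a subject x ROI mean of gwBZ).
#' @param groups factor (or coercible) of group membership.
#' @param covariates data.frame/matrix of numeric covariates (e.g. age,
#'   TIV), or NULL.
#' @return list: `F`, `p`, `df1`, `df2`, `adjustedMeans` (group means at the
#'   grand covariate means), `posthoc` (data.frame: pair, estimate, p_raw,
#'   p_bonf).
#' @export
ancovaGroup <- function(values, groups, covariates = NULL) {
  groups <- droplevels(as.factor(groups))
  n <- length(values)
  stopifnot(n == length(groups), nlevels(groups) >= 2)
  if (any(table(groups) < 2L)) stop("every group needs at least 2 subjects")
  covm <- .covariateMatrix(covariates, n)
  df <- data.frame(y = values, group = groups)
  X <- stats::model.matrix(~ group, df)
  X <- cbind(X, covm)
  if (qr(X)$rank < ncol(X)) stop("design is rank deficient")

  if (ncol(covm) > 0) {
    full <- stats::lm(values ~ groups + covm)
    reduced <- stats::lm(values ~ covm)
  } else {
    full <- stats::lm(values ~ groups)
    reduced <- stats::lm(values ~ 1)
  }
  an <- stats::anova(reduced, full)
  Fstat <- an$F[2]
  p <- an$`Pr(>F)`[2]
  df1 <- an$Df[2]
  df2 <- full$df.residual

  # adjusted means: group coefficient + intercept + covariate part at grand means
  cf <- stats::coef(full)
  covPart <- if (ncol(covm) > 0) sum(cf[-(1:nlevels(groups))] * colMeans(covm)) else 0
  adj <- cf[1] + c(0, cf[2:nlevels(groups)]) + covPart
  names(adj) <- levels(groups)

  V <- stats::vcov(full)
  lv <- levels(groups)
  pairs <- utils::combn(seq_along(lv), 2)
  nPairs <- ncol(pairs)
  posthoc <- data.frame(pair = character(nPairs), estimate = numeric(nPairs),
                        p_raw = numeric(nPairs), p_bonf = numeric(nPairs),
                        stringsAsFactors = FALSE)
  for (j in seq_len(nPairs)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    # contrast of group b vs a in treatment coding (level 1 is reference)
    ctr <- rep(0, length(cf))
    if (a > 1) ctr[a] <- -1
    if (b > 1) ctr[b] <- 1
    est <- sum(ctr * cf)
    se <- sqrt(drop(t(ctr) %*% V %*% ctr))
    t <- est / se
    praw <- 2 * stats::pt(-abs(t), df2)
    posthoc$pair[j] <- paste(lv[a], lv[b], sep = "-")
    posthoc$estimate[j] <- est
    posthoc$p_raw[j] <- praw
    posthoc$p_bonf[j] <- min(1, nPairs * praw)
  }
  list(F = Fstat, p = p, df1 = df1, df2 = df2,
       adjustedMeans = adj, posthoc = posthoc)
}

#' Pearson correlation with t-test p-value
#'
#' @param x,y numeric vectors, n >= 3, nonconstant.
#' @return list: `r`, `p`, `df` (n - 2), `n`, `kind = "pearson"`.
#' @export
pearsonCorr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, df = unname(ct$parameter),
       n = length(x), kind = "pearson")
}

#' Partial correlation adjusted for covariates
#'
#' Residualizes `x` and `y` on an intercept plus the covariates by least
#' squares and correlates the residuals; the t test uses
#' `df = n - 2 - n_covariates`. With no covariates this reduces to the plain
#' Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame/matrix of numeric covariates, or NULL.
#' @return list: `r`, `p`, `df`, `n`, `kind = "partial"`. Constant residuals
#'   give an NA correlation with `flag = "constant residuals"`.
#' @export
partialCorr <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(n == length(y))
  covm <- .covariateMatrix(covariates, n)
  k <- ncol(covm)
  if (n <= 2 + k) stop("need n > 2 + number of covariates")
  X <- cbind(1, covm)
  rx <- stats::lsfit(X, x, intercept = FALSE)$residuals
  ry <- stats::lsfit(X, y, intercept = FALSE)$residuals
  degenerate <- function(r, orig) stats::sd(r) <= 1e-12 * max(1, max(abs(orig)))
  if (degenerate(rx, x) || degenerate(ry, y))
    return(list(r = NA_real_, p = NA_real_, df = n - 2 - k, n = n,
                kind = "partial", flag = "constant residuals"))
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df), df = df, n = n, kind = "partial")
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure; adjusted p-values by the monotone cumulative-minimum
#' construction; rejection at `adjusted <= alpha`.
#'
#' @param pvals numeric vector of p-values in \[0,1\].
#' @param alpha FDR level (default 0.01, the voxelwise setting).
#' @return list: `reject` (logical), `adjusted` (numeric), `alpha`.
#' @export
bhFdr <- function(pvals, alpha = 0.01) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values out of [0,1]")
  adjusted <- stats::p.adjust(pvals, method = "BH")
  list(reject = adjusted <= alpha, adjusted = adjusted, alpha = alpha)
}
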