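# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain loops and first-principles formulas only.

# Triple-loop box convolution (mean over the k^3 neighborhood, zero padding).
oracleBoxConvolve <- function(x, k) {
  h <- (k - 1) / 2
  d <- dim(x)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
    s <- 0
    for (di in -h:h) for (dj in -h:h) for (dl in -h:h) {
      ii <- i + di; jj <- j + dj; ll <- l + dl
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] && ll >= 1 && ll <= d[3])
        s <- s + x[ii, jj, ll]
    }
    out[i, j, l] <- s / k^3
  }
  out
}

# Pool thresholds recomputed by explicit voxel enumeration.
oracleThresholds <- function(t1arr, gmarr, wmarr) {
  gmPool <- c(); wmPool <- c()
  d <- dim(t1arr)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
    if (gmarr[i, j, l] > 0.5) gmPool <- c(gmPool, t1arr[i, j, l])
    if (wmarr[i, j, l] > 0.5) wmPool <- c(wmPool, t1arr[i, j, l])
  }
  sdv <- function(v) sqrt(sum((v - mean(v))^2) / (length(v) - 1))
  list(lower = mean(gmPool) + sdv(gmPool),
       upper = mean(wmPool) - sdv(wmPool),
       gmMean = mean(gmPool), wmMean = mean(wmPool))
}

# ANCOVA partial F of the group factor by explicit residual-sum-of-squares
# comparison, solving the normal equations directly.
oracleAncovaF <- function(y, groups, covm) {
  groups <- as.factor(groups)
  n <- length(y)
  G <- outer(groups, levels(groups)[-1], `==`) * 1
  Xf <- cbind(1, G, covm)
  Xr <- cbind(1, covm)
  rss <- function(X) {
    b <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% b)^2)
  }
  RSSf <- rss(Xf); RSSr <- rss(Xr)
  q <- nlevels(groups) - 1
  dfRes <- n - ncol(Xf)
  list(F = ((RSSr - RSSf) / q) / (RSSf / dfRes), df1 = q, df2 = dfRes)
}

# BH rejections by exhaustive scan of every step-up threshold.
oracleBH <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  kmax <- 0
  for (k in seq_len(m)) if (ps[k] <= k * alpha / m) kmax <- k
  reject <- rep(FALSE, m)
  if (kmax > 0) reject[ord[seq_len(kmax)]] <- TRUE
  reject
}

# AUC as the normalized count of case-control pairs ranked correctly
# (ties count 1/2).
oracleAUC <- function(score, isCase) {
  cases <- score[isCase]
  ctrls <- score[!isCase]
  tot <- 0
  for (a in cases) for (b in ctrls)
    tot <- tot + (if (a > b) 1 else if (a == b) 0.5 else 0)
  tot / (length(cases) * length(ctrls))
}

# Connected components by iterated min-label propagation to a fixed point
# (a different algorithm from the package's frontier flood fill).
oracleLabelComponents <- function(mask, connectivity) {
  d <- dim(mask)
  maxAbs <- c("6" = 1, "18" = 2, "26" = 3)[[as.character(connectivity)]]
  lab <- array(0, d)
  lab[mask] <- seq_len(sum(mask))
  idx <- which(mask)
  pos <- arrayInd(idx, d)
  repeat {
    changed <- FALSE
    for (v in seq_along(idx)) {
      p <- pos[v, ]
      best <- lab[idx[v]]
      for (di in -1:1) for (dj in -1:1) for (dl in -1:1) {
        if (abs(di) + abs(dj) + abs(dl) == 0 ||
            abs(di) + abs(dj) + abs(dl) > maxAbs) next
        q <- p + c(di, dj, dl)
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] < best)
          best <- lab[q[1], q[2], q[3]]
      }
      if (best < lab[idx[v]]) { lab[idx[v]] <- best; changed <- TRUE }
    }
    if (!changed) break
  }
  # canonicalize labels to 1..k in first-seen order
  u <- unique(lab[idx])
  out <- array(0L, d)
  out[idx] <- match(lab[idx], u)
  out
}

# Same-partition check for two labelings.
samePartition <- function(labA, labB) {
  idx <- which(labA != 0)
  if (!identical(which(labB != 0), idx)) return(FALSE)
  a <- labA[idx]; b <- labB[idx]
  all(tapply(b, a, function(v) length(unique(v))) == 1) &&
    all(tapply(a, b, function(v) length(unique(v))) == 1)
}
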