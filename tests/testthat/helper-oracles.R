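# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: kernels are rebuilt from the distance definition, rank
# tests are enumerated over all sign assignments / group labelings, and
# the BH step-up rule is applied literally from its definition.

# Exhaustive sphere peak/trough: for every in-mask candidate center, scan
# a bounding box and average all voxels whose center lies within the
# sphere radius; centers whose sphere leaves the image are skipped.
oraclePeakSphere <- function(vals, mask, spacing, targetML = 1,
                             mode = "max") {
  r <- (3 * targetML * 1000 / (4 * pi))^(1 / 3)
  dims <- dim(vals)
  half <- floor(r / spacing)
  cand <- which(mask, arr.ind = TRUE)
  best <- NULL
  for (ci in seq_len(nrow(cand))) {
    cc <- cand[ci, ]
    vv <- c()
    ok <- TRUE
    for (dx in -half[1]:half[1]) for (dy in -half[2]:half[2])
      for (dz in -half[3]:half[3]) {
        if ((dx * spacing[1])^2 + (dy * spacing[2])^2 +
            (dz * spacing[3])^2 > r^2) next
        p <- cc + c(dx, dy, dz)
        if (any(p < 1) || any(p > dims)) { ok <- FALSE; break }
        vv <- c(vv, vals[p[1], p[2], p[3]])
      }
    if (!ok) next
    m <- mean(vv)
    if (is.null(best) || (mode == "max" && m > best) ||
        (mode == "min" && m < best)) best <- m
  }
  best
}

# Literal threshold definition of the percent isocontour.
oracleIsocontour <- function(vals, mask, fraction) {
  thr <- fraction * max(vals[mask])
  mask & (vals >= thr)
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments
# of the ranked |d| (zero differences removed by the caller).
oracleSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  allV <- as.vector(signs %*% rk)
  min(1, 2 * min(mean(allV <= v), mean(allV >= v)))
}

# Exact two-sided Mann-Whitney p by enumerating all C(n+m, n) labelings.
oracleMannWhitneyP <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(length(pooled), na)
  allU <- apply(combs, 2, function(ix) sum(rk[ix]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(allU <= u), mean(allU >= u)))
}

# Literal BH step-up: sort ascending, find the largest k with
# p(k) <= k q / m, reject everything at or below it.
oracleBH <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  reject <- rep(FALSE, m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  reject
}

# Small random phantom pieces shared by several tests.
randomMaskedVolume <- function(dims = c(10, 10, 8), spacing = c(2, 2, 3),
                               kind = "SUV_g_per_mL", pMask = 0.3) {
  vals <- array(stats::runif(prod(dims), 0.5, 10), dims)
  mask <- array(stats::runif(prod(dims)) < pMask, dims)
  if (!any(mask)) mask[ceiling(dims[1] / 2), ceiling(dims[2] / 2),
                       ceiling(dims[3] / 2)] <- TRUE
  list(volume = VolumeImage(vals, spacing, kind),
       mask = RoiMask(mask, spacing), vals = vals, maskArr = mask,
       spacing = spacing)
}
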