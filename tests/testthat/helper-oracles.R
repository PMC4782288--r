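# Independent brute-force oracles used to pin the morphometry primitives and
# the exact rank test.  These deliberately share no code with the package
# implementations.

# exact nearest-feature Euclidean distance by exhaustive search
bruteForceEDT <- function(featureMask) {
  d <- dim(featureMask)
  co <- which(featureMask, arr.ind = TRUE)
  if (nrow(co) == 0) return(array(Inf, d))
  g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                             z = seq_len(d[3])))
  out <- numeric(nrow(g))
  step <- 4096
  for (s in seq(1, nrow(g), by = step)) {
    idx <- s:min(s + step - 1, nrow(g))
    block <- g[idx, , drop = FALSE]
    d2 <- outer(block[, 1], co[, 1], "-")^2 +
          outer(block[, 2], co[, 2], "-")^2 +
          outer(block[, 3], co[, 3], "-")^2
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  array(out, d)
}

# brute-force largest-inscribed-sphere thickness: for every mask voxel c the
# sphere radius is its distance to the nearest background voxel (volume
# border counts as background); thickness(p) = 2 * max over spheres strictly
# containing p.
bruteForceLocalThickness <- function(mask) {
  d <- dim(mask)
  co <- which(mask, arr.ind = TRUE)
  out <- array(0, d)
  if (nrow(co) == 0) return(out)
  bg <- which(!mask, arr.ind = TRUE)
  # squared radii kept as exact integers so the strict open-ball comparison
  # has no floating-point boundary ambiguity
  radii2 <- numeric(nrow(co))
  for (i in seq_len(nrow(co))) {
    p <- co[i, ]
    dBorder2 <- min(p, d - p + 1)^2   # nearest outside voxel centre
    dBg2 <- if (nrow(bg) > 0)
      min((bg[, 1] - p[1])^2 + (bg[, 2] - p[2])^2 + (bg[, 3] - p[3])^2)
    else Inf
    radii2[i] <- min(dBorder2, dBg2)
  }
  for (i in seq_len(nrow(co))) {
    c0 <- co[i, ]
    inSphere <- (co[, 1] - c0[1])^2 + (co[, 2] - c0[2])^2 +
                (co[, 3] - c0[3])^2 < radii2[i]
    sel <- co[inSphere, , drop = FALSE]
    cur <- out[sel]
    out[sel] <- pmax(cur, 2 * sqrt(radii2[i]))
  }
  out
}

# exact two-tailed Mann-Whitney p by enumerating every assignment of the
# pooled values to group A; U computed by pair counting (independent of the
# rank-sum formula used in the package).
enumerationMWOracle <- function(a, b) {
  pool <- c(a, b)
  na <- length(a); n <- length(pool)
  uOf <- function(idxA) {
    xa <- pool[idxA]; xb <- pool[-idxA]
    sum(outer(xa, xb, ">")) + 0.5 * sum(outer(xa, xb, "=="))
  }
  cmb <- combn(n, na)
  us <- apply(cmb, 2, uOf)
  uObs <- uOf(seq_len(na))
  pLe <- mean(us <= uObs); pGe <- mean(us >= uObs)
  min(1, 2 * min(pLe, pGe))
}

# full width at half maximum of a single peak by linear interpolation
measureFWHM <- function(x, y) {
  pk <- which.max(y)
  half <- y[pk] / 2
  left <- max(which(y[1:pk] <= half))
  right <- pk - 1 + min(which(y[pk:length(y)] <= half))
  xl <- x[left] + (x[left + 1] - x[left]) * (half - y[left]) /
    (y[left + 1] - y[left])
  xr <- x[right - 1] + (x[right] - x[right - 1]) * (half - y[right - 1]) /
    (y[right] - y[right - 1])
  abs(xr - xl)
}

# random sparse 3D test mask
randomMask <- function(dims, pFeature = 0.03, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- array(runif(prod(dims)) < pFeature, dims)
  if (!any(m)) m[ceiling(dims[1] / 2), ceiling(dims[2] / 2),
                 ceiling(dims[3] / 2)] <- TRUE
  m
}

# random blobby 3D mask (union of a few balls) for thickness oracles
randomBlobMask <- function(dims, nBalls = 3, rRange = c(2, 5), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                             seq_len(dims[3])))
  m <- array(FALSE, dims)
  rMax <- min(rRange[2], (min(dims) - 3) / 2)   # ball must fit the volume
  for (i in seq_len(nBalls)) {
    r <- runif(1, min(rRange[1], rMax), rMax)
    cen <- runif(3, 1 + r, dims - r)
    m <- m | array(colSums((t(g) - cen)^2) <= r^2, dims)
  }
  m
}
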