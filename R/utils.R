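## Internal helpers shared across modules.

# Evaluate expr under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched, making every generator a pure function of its
# arguments.  seed = NULL leaves the global stream in charge.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Otsu threshold on a numeric vector (256-bin histogram); returns the
# threshold value maximizing between-class variance.
otsuThreshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(nbins, floor((x - r[1]) / diff(r) * nbins) + 1L), nbins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  sigma2 <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sigma2[!is.finite(sigma2)] <- -Inf
  mids[which.max(sigma2)]
}

# Percentile by linear interpolation between order statistics
# (quantile type 7, pinned here so tests can rely on it).
interpPercentile <- function(x, prob) {
  as.numeric(quantile(x, probs = prob, type = 7, names = FALSE))
}

# Rasterize a capsule (tube segment with hemispherical caps) into a logical
# 3D mask: voxels whose centre lies within `radius` of the segment p0-p1
# (coordinates and radius in voxel units, 1-based voxel centres).
rasterizeTubeMask <- function(shape, p0, p1, radius) {
  lo <- pmax(1, floor(pmin(p0, p1) - radius))
  hi <- pmin(shape, ceiling(pmax(p0, p1) + radius))
  if (any(lo > hi)) return(array(FALSE, shape))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  d <- p1 - p0
  len2 <- sum(d^2)
  px <- g$x - p0[1]; py <- g$y - p0[2]; pz <- g$z - p0[3]
  if (len2 == 0) {
    dist2 <- px^2 + py^2 + pz^2
  } else {
    t <- pmin(1, pmax(0, (px * d[1] + py * d[2] + pz * d[3]) / len2))
    dist2 <- (px - t * d[1])^2 + (py - t * d[2])^2 + (pz - t * d[3])^2
  }
  inside <- dist2 <= radius^2
  mask <- array(FALSE, shape)
  idx <- cbind(g$x[inside], g$y[inside], g$z[inside])
  mask[idx] <- TRUE
  mask
}

# 2D capsule rasterizer (pixel centres within half-width of segment).
rasterizeCapsule2D <- function(shape, p0, p1, halfWidth) {
  m <- rasterizeTubeMask(c(shape, 1L), c(p0, 1), c(p1, 1), halfWidth)
  m[, , 1]
}

# Distance (pixels) from every pixel of a 2D grid to segment p0-p1.
segmentDistance2D <- function(shape, p0, p1) {
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]))
  d <- p1 - p0
  len2 <- sum(d^2)
  px <- g$x - p0[1]; py <- g$y - p0[2]
  if (len2 == 0) {
    dist <- sqrt(px^2 + py^2)
  } else {
    t <- pmin(1, pmax(0, (px * d[1] + py * d[2]) / len2))
    dist <- sqrt((px - t * d[1])^2 + (py - t * d[2])^2)
  }
  matrix(dist, shape[1], shape[2])
}

# squared EDT wrapper returning distances in voxel units
edtVoxels <- function(featureMask) {
  d <- dim(featureMask)
  if (length(d) == 2L) {
    featureMask <- array(featureMask, c(d, 1L))
    d <- dim(featureMask)
  }
  out <- sqrt(.edt3d_sq(as.logical(featureMask), as.integer(d)))
  array(out, d)
}

# connected components (26-connectivity in 3D / 8-connectivity in 2D)
labelComponents <- function(mask) {
  d <- dim(mask)
  two_d <- length(d) == 2L
  if (two_d) {
    mask <- array(mask, c(d, 1L))
    d <- dim(mask)
  }
  lab <- array(.label3d(as.logical(mask), as.integer(d)), d)
  if (two_d) lab[, , 1] else lab
}

stopifnot_msg <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
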