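## Synthetic micro-CT vascular phantoms: random-walk branching tube trees
## rasterized into a bright-vessel volume with known ground truth.

#' Ground-truth record attached to every phantom
#'
#' @param ... named ground-truth fields; unspecified fields are `NA`.
#' @return list of class `PhantomGroundTruth` with the standard fields
#'   (`trueFbv`, `vesselRadiiUm`, `trueFev`, `nucleusCountInVessel`,
#'   `nucleusCountTotal`, `vesselAreaPx`, `immatureAreaPx`, `classEffects`,
#'   `seed`) plus any extras supplied.
#' @export
phantomTruth <- function(...) {
  fields <- list(trueFbv = NA_real_, vesselRadiiUm = numeric(0),
                 trueFev = NA_real_, nucleusCountInVessel = NA_integer_,
                 nucleusCountTotal = NA_integer_, vesselAreaPx = NA_integer_,
                 immatureAreaPx = NA_integer_, classEffects = list(),
                 seed = NA_integer_)
  extra <- list(...)
  fields[names(extra)] <- extra
  structure(fields, class = "PhantomGroundTruth")
}

# one random tube tree as a segment table (voxel coordinates and radii)
randomTubeTree <- function(shape, nSegments, radiusRangeVox, segmentLengthVox,
                           branchProb) {
  segs <- vector("list", nSegments)
  # queue of growth tips: position + direction + radius
  randDir <- function() {
    v <- rnorm(3)
    v / sqrt(sum(v^2))
  }
  tips <- list(list(
    pos = runif(3, 0.25, 0.75) * shape,
    dir = randDir(),
    radius = runif(1, radiusRangeVox[1], radiusRangeVox[2])))
  k <- 0
  while (k < nSegments) {
    if (length(tips) == 0) {
      tips <- list(list(pos = runif(3, 0.25, 0.75) * shape, dir = randDir(),
                        radius = runif(1, radiusRangeVox[1], radiusRangeVox[2])))
    }
    i <- sample.int(length(tips), 1)
    tip <- tips[[i]]
    tips[[i]] <- NULL
    newDir <- tip$dir + 0.4 * rnorm(3)
    newDir <- newDir / sqrt(sum(newDir^2))
    p1 <- tip$pos + newDir * segmentLengthVox
    # reflect at a margin so tubes stay inside the volume
    margin <- tip$radius + 2
    for (ax in 1:3) {
      if (p1[ax] < margin) { p1[ax] <- 2 * margin - p1[ax]; newDir[ax] <- -newDir[ax] }
      if (p1[ax] > shape[ax] - margin) {
        p1[ax] <- 2 * (shape[ax] - margin) - p1[ax]; newDir[ax] <- -newDir[ax]
      }
    }
    k <- k + 1
    segs[[k]] <- c(tip$pos, p1, tip$radius)
    nextRadius <- max(radiusRangeVox[1],
                      min(radiusRangeVox[2], tip$radius * runif(1, 0.85, 1.05)))
    tips[[length(tips) + 1]] <- list(pos = p1, dir = newDir, radius = nextRadius)
    if (runif(1) < branchProb) {
      bd <- newDir + rnorm(3)
      bd <- bd / sqrt(sum(bd^2))
      tips[[length(tips) + 1]] <- list(
        pos = p1, dir = bd,
        radius = max(radiusRangeVox[1], nextRadius * runif(1, 0.6, 0.9)))
    }
  }
  do.call(rbind, segs)
}

#' Generate a vascular phantom volume with exact ground truth
#'
#' Builds a random-walk branching tube tree (bright vessels on a dark
#' background), rasterizes it exactly (a voxel is vessel when its centre
#' lies within the segment radius), and adds Gaussian noise.  The ground
#' truth records the exact rasterized vessel mask, per-segment radii, and
#' the exact voxel-count vessel volume fraction.
#'
#' @param shape volume dimensions in voxels (each >= 32).
#' @param voxelSizeUm isotropic voxel size in micrometres (default 9,
#'   matching the acquisition the phantom emulates).
#' @param nSegments number of tube segments to grow (default 60); ignored
#'   when `targetFbv` is given.
#' @param radiusRangeUm segment radius range in micrometres (default
#'   c(18, 90)); the minimum must be at least one voxel and the maximum at
#'   most a quarter of the smallest volume edge.
#' @param targetFbv optional target vessel volume fraction; segments are
#'   added until the rasterized fraction reaches it.
#' @param segmentLengthUm tube segment length (default 110).
#' @param branchProb branching probability per segment (default 0.3).
#' @param vesselIntensity,backgroundIntensity grayscale levels of vessel
#'   and background.
#' @param noiseSd additive Gaussian noise SD (same units as intensities).
#' @param seed integer seed; identical arguments and seed give a
#'   bit-identical phantom.
#' @return list with `volume` (a [VolumeImage]), `vesselMask` (exact
#'   logical ground-truth mask) and `truth` (a `PhantomGroundTruth`).
#' @export
generateVascularPhantom <- function(shape = c(64, 64, 64), voxelSizeUm = 9,
                                    nSegments = 60, radiusRangeUm = c(18, 90),
                                    targetFbv = NULL, segmentLengthUm = 110,
                                    branchProb = 0.3, vesselIntensity = 1,
                                    backgroundIntensity = 0.1, noiseSd = 0.02,
                                    seed = NULL) {
  shape <- as.integer(shape)
  if (any(shape < 32)) stop("phantom volumes must be at least 32 voxels per axis")
  radiusRangeVox <- radiusRangeUm / voxelSizeUm
  if (radiusRangeVox[1] < 1) stop("minimum radius must be at least one voxel")
  if (radiusRangeVox[2] > min(shape) / 4)
    stop("degenerate geometry: maximum radius exceeds a quarter of the volume")
  segmentLengthVox <- segmentLengthUm / voxelSizeUm

  withSeed(seed, {
    mask <- array(FALSE, shape)
    radii <- numeric(0)
    if (!is.null(targetFbv)) {
      stopifnot(targetFbv > 0, targetFbv < 1)
      nv <- prod(shape)
      while (sum(mask) / nv < targetFbv) {
        segs <- randomTubeTree(shape, 4L, radiusRangeVox, segmentLengthVox,
                               branchProb)
        for (i in seq_len(nrow(segs))) {
          # budget each segment to a fraction of the remaining volume so the
          # realized fraction converges to the target without overshooting
          # (capsule volume = pi r^2 L + 4/3 pi r^3)
          remaining <- (targetFbv - sum(mask) / nv) * nv
          segLen <- sqrt(sum((segs[i, 4:6] - segs[i, 1:3])^2)) + 1
          allowed <- 0.7 * remaining
          rCap <- sqrt(allowed / (pi * segLen))
          for (it in 1:3) rCap <- sqrt(allowed / (pi * (segLen + 4 / 3 * rCap)))
          r <- min(segs[i, 7], max(radiusRangeVox[1], rCap))
          mask <- mask | rasterizeTubeMask(shape, segs[i, 1:3], segs[i, 4:6], r)
          radii <- c(radii, r * voxelSizeUm)
          if (sum(mask) / nv >= targetFbv) break
        }
      }
    } else if (nSegments > 0) {
      segs <- randomTubeTree(shape, as.integer(nSegments), radiusRangeVox,
                             segmentLengthVox, branchProb)
      for (i in seq_len(nrow(segs))) {
        mask <- mask | rasterizeTubeMask(shape, segs[i, 1:3], segs[i, 4:6],
                                         segs[i, 7])
      }
      radii <- segs[, 7] * voxelSizeUm
    }
    vox <- array(backgroundIntensity, shape)
    vox[mask] <- vesselIntensity
    if (noiseSd > 0) vox <- vox + array(rnorm(prod(shape), 0, noiseSd), shape)
    truth <- phantomTruth(
      trueFbv = sum(mask) / prod(shape),
      vesselRadiiUm = radii,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
    list(volume = VolumeImage(vox, voxelSizeUm),
         vesselMask = mask, truth = truth)
  })
}
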