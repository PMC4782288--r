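## Micro-CT vascular morphometry: Hessian vesselness segmentation, fractional
## blood volume, local-thickness vessel calibers and distance-to-nearest-vessel
## maps.  All physical quantities are in micrometres; voxels are isotropic.

gaussianKernel1D <- function(sigma, order = 0L) {
  r <- max(1L, ceiling(3.5 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
    "0" = g,
    "1" = -x / sigma^2 * g,
    "2" = {
      k <- (x^2 - sigma^2) / sigma^4 * g
      k - mean(k)   # exact zero response on constant input
    },
    stop("unsupported derivative order"))
}

# Hessian of a 3D volume from separable Gaussian derivative filters at a
# single scale sigma (voxels); gamma-normalized (gamma = 2) so responses are
# comparable across scales.
gaussianHessian <- function(vol, sigma) {
  d <- dim(vol)
  k0 <- gaussianKernel1D(sigma, 0L)
  k1 <- gaussianKernel1D(sigma, 1L)
  k2 <- gaussianKernel1D(sigma, 2L)
  cv <- function(v, k, ax) .conv1d_axis(v, as.integer(d), k, as.integer(ax))
  v <- as.numeric(vol)
  s2 <- sigma^2
  list(
    xx = s2 * cv(cv(cv(v, k2, 0), k0, 1), k0, 2),
    yy = s2 * cv(cv(cv(v, k0, 0), k2, 1), k0, 2),
    zz = s2 * cv(cv(cv(v, k0, 0), k0, 1), k2, 2),
    xy = s2 * cv(cv(cv(v, k1, 0), k1, 1), k0, 2),
    xz = s2 * cv(cv(cv(v, k1, 0), k0, 1), k1, 2),
    yz = s2 * cv(cv(cv(v, k0, 0), k1, 1), k1, 2))
}

# Frangi tubularity measure for bright tubes at one scale.
frangiResponse <- function(hess, alpha = 0.5, beta = 0.5, c = NULL) {
  ev <- .eig3_sym(hess$xx, hess$yy, hess$zz, hess$xy, hess$xz, hess$yz)
  l1 <- ev[, 1]; l2 <- ev[, 2]; l3 <- ev[, 3]
  s <- sqrt(l1^2 + l2^2 + l3^2)
  if (is.null(c)) c <- max(s) / 2
  if (!is.finite(c) || c < 1e-12) return(numeric(length(l1)))
  ra <- abs(l2) / pmax(abs(l3), .Machine$double.eps)
  rb <- abs(l1) / pmax(sqrt(abs(l2 * l3)), .Machine$double.eps)
  v <- (1 - exp(-ra^2 / (2 * alpha^2))) *
       exp(-rb^2 / (2 * beta^2)) *
       (1 - exp(-s^2 / (2 * c^2)))
  v[l2 >= 0 | l3 >= 0] <- 0  # bright tubes: both cross-sectional curvatures < 0
  v
}

#' Segment vasculature with a multiscale Hessian vesselness filter
#'
#' Computes a Frangi-type tubularity response for bright tubular structures
#' at each requested scale (Gaussian-derivative Hessian, gamma-normalized),
#' takes the voxel-wise maximum over scales, rescales it to `[0, 1]`, and
#' thresholds it within the tumor mask (Otsu by default) with small-component
#' removal.
#'
#' @param volume a [VolumeImage].
#' @param scales analysis scales in micrometres (converted to Gaussian sigmas
#'   in voxel units internally); default `c(9, 18, 36, 72)`, matched to a
#'   9 um isotropic acquisition.
#' @param alpha,beta Frangi plate/blob discrimination parameters.
#' @param threshold either `"otsu"` (data-driven threshold on the vesselness
#'   values inside the tumor mask) or a numeric threshold in `[0, 1]`.
#' @param hysteresisLow fraction of the main threshold used as the low cut
#'   of hysteresis thresholding: voxels above `hysteresisLow * threshold`
#'   are kept when connected to a voxel above the main threshold.  The
#'   tubularity response tapers towards a tube's surface, so a single hard
#'   cut keeps only vessel cores; the connected low cut restores the full
#'   caliber without admitting isolated background.  Set to 1 to disable.
#' @param intensityGate if `TRUE` (default), the vessel mask is additionally
#'   restricted to voxels whose image intensity exceeds an Otsu threshold on
#'   the tumor voxels.  The tubularity response spreads about a voxel beyond
#'   a tube's surface (Gaussian smoothing), producing a dim halo; for
#'   contrast-cast vasculature the bright lumen itself delineates the vessel,
#'   so gating on intensity removes the halo without touching true vessel
#'   voxels.  Disable for volumes where vessels are not reliably bright.
#' @param minComponentVoxels connected components (26-connectivity) smaller
#'   than this are removed from the vessel mask; default 27.
#' @return a [VesselSegmentation].
#' @export
vesselnessFilter <- function(volume, scales = c(9, 18, 36, 72),
                             alpha = 0.5, beta = 0.5,
                             threshold = "otsu", hysteresisLow = 0.35,
                             intensityGate = TRUE,
                             minComponentVoxels = 27L) {
  stopifnot(is(volume, "VolumeImage"))
  if (length(scales) < 1) stop("at least one scale is required")
  sigmas <- scales / voxelSize(volume)
  if (any(sigmas < 1)) stop("scales below one voxel are not supported")
  vol <- volume@voxels
  d <- dim(vol)
  resp <- numeric(prod(d))
  for (s in sigmas) {
    h <- gaussianHessian(vol, s)
    resp <- pmax(resp, frangiResponse(h, alpha, beta))
  }
  mx <- max(resp)
  if (mx > 0) resp <- resp / mx
  vmap <- array(resp, d)

  inTumor <- volume@tumorMask
  vals <- vmap[inTumor]
  thr <- if (identical(threshold, "otsu")) {
    if (all(vals == 0)) Inf else otsuThreshold(vals)
  } else as.numeric(threshold)
  core <- vmap >= thr & inTumor & vmap > 0
  if (hysteresisLow < 1 && any(core)) {
    low <- vmap >= hysteresisLow * thr & inTumor & vmap > 0
    lab <- labelComponents(low)
    keep <- unique(lab[core])
    mask <- low & array(lab %in% keep[keep > 0], d)
  } else {
    mask <- core
  }
  if (intensityGate && any(mask)) {
    gate <- otsuThreshold(vol[inTumor])
    mask <- mask & vol >= gate
  }
  if (any(mask) && minComponentVoxels > 1) {
    lab <- labelComponents(mask)
    keep <- which(tabulate(lab[lab > 0]) >= minComponentVoxels)
    mask <- array(lab %in% keep, d) & mask
  }
  new("VesselSegmentation", vesselness = vmap, vesselMask = mask,
      scales = as.numeric(scales), threshold = as.numeric(thr),
      voxelSize = voxelSize(volume))
}

#' Fractional blood volume
#'
#' FBV = segmented vessel volume / tumor volume, computed as the voxel-count
#' ratio `|vessel mask within tumor| / |tumor mask|`.
#'
#' @param seg a [VesselSegmentation] (or a logical 3D vessel mask).
#' @param volume the [VolumeImage] providing the tumor mask.
#' @return the fractional blood volume in `[0, 1]`.
#' @export
computeFBV <- function(seg, volume) {
  mask <- if (is(seg, "VesselSegmentation")) vesselMask(seg) else seg
  tm <- tumorMask(volume)
  nTumor <- sum(tm)
  if (nTumor == 0) stop("empty tumor mask")
  sum(mask & tm) / nTumor
}

#' Local thickness (vessel caliber) map
#'
#' Thickness at a voxel is the diameter of the largest sphere fully
#' contained in the mask that covers the voxel (the standard
#' largest-inscribed-sphere definition used for trabecular and vascular
#' caliber morphometry).  The volume border is treated as background.
#'
#' @param mask logical 3D array (vessel mask).
#' @param voxelSize voxel edge length in micrometres.
#' @return 3D numeric array of local thickness in micrometres (0 outside
#'   the mask).
#' @export
localThickness <- function(mask, voxelSize = 1) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  if (!any(mask)) return(array(0, d))
  # pad with one background layer so out-of-volume counts as background
  pd <- d + 2L
  padded <- array(FALSE, pd)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  r2 <- .edt3d_sq(as.logical(!padded), as.integer(pd))
  lt <- .local_thickness(as.logical(padded), as.integer(pd), r2)
  lt <- array(lt, pd)[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  lt * voxelSize
}

#' Vessel caliber summary metrics
#'
#' Summarizes a per-voxel caliber (local thickness) distribution: the 90th
#' percentile (linear interpolation between order statistics), the fraction
#' of vessel voxels with caliber strictly greater than a cut-off (150 um by
#' default; a voxel at exactly the cut-off is not counted), and a normalized
#' histogram.
#'
#' @param thickness local-thickness map (um) or vector of per-voxel calibers;
#'   zeros (non-vessel voxels) are ignored.
#' @param largeCutUm caliber cut-off in micrometres (default 150).
#' @param breaks histogram breaks in micrometres (default 0 to the data
#'   maximum in 9 um steps).
#' @return list with `vcValues`, `vcP90`, `fracVcGtCut`, `histogram`
#'   (data.frame mid/density normalized to unit sum), and `cutUm`.
#' @export
caliberMetrics <- function(thickness, largeCutUm = 150, breaks = NULL) {
  vc <- as.numeric(thickness)
  vc <- vc[vc > 0]
  if (length(vc) == 0) stop("no vessel voxels: caliber metrics undefined")
  if (is.null(breaks)) breaks <- seq(0, max(vc) + 9, by = 9)
  h <- hist(vc, breaks = breaks, plot = FALSE)
  list(
    vcValues = vc,
    vcP90 = interpPercentile(vc, 0.90),
    fracVcGtCut = mean(vc > largeCutUm),
    histogram = data.frame(mid = h$mids, density = h$counts / sum(h$counts)),
    cutUm = largeCutUm)
}

#' Distance-to-nearest-vessel metrics
#'
#' Computes the exact Euclidean distance from every non-vessel tumor voxel
#' to the nearest vessel voxel (in micrometres) and summary statistics over
#' those voxels: the median, the 90th percentile, and the fraction of
#' non-vessel tumor voxels farther than a cut-off (200 um by default, the
#' upper bound of the oxygen diffusion distance).  Vessel voxels (distance 0)
#' are excluded from the summaries.
#'
#' @param seg a [VesselSegmentation] or logical 3D vessel mask.
#' @param volume the [VolumeImage] providing tumor mask and voxel size.
#' @param farCutUm distance cut-off in micrometres (default 200).
#' @return list with `dnvMap` (um; 0 on vessel voxels, NA outside the tumor),
#'   `dnvValues`, `dnvMedian`, `dnvP90`, `fracDnvGtCut`, `histogram`, `cutUm`.
#' @export
dnvMetrics <- function(seg, volume, farCutUm = 200) {
  mask <- if (is(seg, "VesselSegmentation")) vesselMask(seg) else seg
  tm <- tumorMask(volume)
  if (!any(mask)) stop("empty vessel mask: all distances are infinite")
  dv <- edtVoxels(mask) * voxelSize(volume)
  dnvMap <- dv
  dnvMap[!tm] <- NA_real_
  vals <- dv[tm & !mask]
  h <- hist(vals, breaks = seq(0, max(vals) + 18, by = 18), plot = FALSE)
  list(
    dnvMap = dnvMap,
    dnvValues = vals,
    dnvMedian = median(vals),
    dnvP90 = interpPercentile(vals, 0.90),
    fracDnvGtCut = mean(vals > farCutUm),
    histogram = data.frame(mid = h$mids, density = h$counts / sum(h$counts)),
    cutUm = farCutUm)
}

#' Full micro-CT morphometry for one tumor volume
#'
#' Convenience wrapper running vesselness segmentation, FBV, caliber and
#' distance metrics with the package defaults.
#'
#' @param volume a [VolumeImage].
#' @param scales vesselness scales in micrometres.
#' @param ... passed to [vesselnessFilter()].
#' @return list with `segmentation`, `fbv`, `caliber`, `dnv`.
#' @export
microctMorphometry <- function(volume, scales = c(9, 18, 36, 72), ...) {
  seg <- vesselnessFilter(volume, scales = scales, ...)
  if (!any(vesselMask(seg)))
    return(list(segmentation = seg, fbv = 0, caliber = NULL, dnv = NULL))
  lt <- localThickness(vesselMask(seg), voxelSize(volume))
  list(
    segmentation = seg,
    fbv = computeFBV(seg, volume),
    caliber = caliberMetrics(lt[vesselMask(seg)]),
    dnv = dnvMetrics(seg, volume))
}
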