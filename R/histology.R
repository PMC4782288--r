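## Double-stain histology quantification: HSV threshold segmentation of
## lectin (endothelium), Ki67 (proliferation) and alpha-SMA (pericyte)
## stains, marker-based watershed separation of overlapping nuclei,
## proliferating-endothelial-cell density and the pericyte-negative
## (immature) vessel area fraction.

#' Default hue/saturation threshold bands per stain
#'
#' One fixed band set is applied to every field of a study (the bands play
#' the role of the manually determined thresholds of a stained cohort).
#' Hue and saturation are normalized to `[0, 1]`; value limits default to
#' the full range.
#'
#' @return named list of band lists (`h`, `s`, `v` each a length-2 range)
#'   for `lectin` (blue), `ki67` (brown) and `sma` (brick red).
#' @export
defaultStainBands <- function() {
  list(
    lectin = list(h = c(0.52, 0.75), s = c(0.25, 1), v = c(0.15, 1)),
    ki67   = list(h = c(0.03, 0.14), s = c(0.35, 1), v = c(0.15, 0.92)),
    sma    = list(h = c(0.86, 0.995), s = c(0.35, 1), v = c(0.15, 0.95)))
}

checkBands <- function(bands) {
  for (nm in names(bands)) {
    b <- bands[[nm]]
    for (ch in c("h", "s")) {
      r <- b[[ch]]
      if (is.null(r) || length(r) != 2 || any(r < 0) || any(r > 1) || r[1] > r[2])
        stop(sprintf("invalid %s band for stain '%s': must be a range in [0, 1]",
                     ch, nm))
    }
  }
  invisible(TRUE)
}

pixelsInBand <- function(h, s, v, band) {
  ok <- h >= band$h[1] & h <= band$h[2] & s >= band$s[1] & s <= band$s[2]
  if (!is.null(band$v)) ok <- ok & v >= band$v[1] & v <= band$v[2]
  ok
}

#' Segment stains by hue and saturation
#'
#' Converts the RGB field to HSV and classifies each pixel by membership of
#' fixed hue/saturation(/value) bands, one band set for the whole study.
#'
#' @param field a [StainField].
#' @param bands band list as returned by [defaultStainBands()]; only the
#'   stains named here are segmented.
#' @return list of class `StainMasks` with one logical matrix per stain and
#'   a `thresholds` element recording the bands applied.
#' @export
segmentStains <- function(field, bands = defaultStainBands()) {
  stopifnot(is(field, "StainField"))
  checkBands(bands)
  d <- dim(field@rgb)
  rgbMat <- rbind(
    as.vector(field@rgb[, , 1]),
    as.vector(field@rgb[, , 2]),
    as.vector(field@rgb[, , 3]))
  hsvMat <- rgb2hsv(rgbMat, maxColorValue = 1)
  masks <- lapply(bands, function(b) {
    matrix(pixelsInBand(hsvMat[1, ], hsvMat[2, ], hsvMat[3, ], b), d[1], d[2])
  })
  structure(c(masks, list(thresholds = bands)), class = "StainMasks")
}

#' Separate touching nuclei by marker-based watershed
#'
#' Markers are the regional maxima of the interior Euclidean distance
#' transform of the nucleus mask (detected within a neighbourhood of half
#' the expected nucleus radius), and touching nuclei are split by a
#' watershed on the distance map.
#'
#' @param ki67Mask logical matrix of nucleus-positive pixels.
#' @param expectedDiameterPx expected nucleus diameter in pixels; sets the
#'   marker detection neighbourhood (default 16).
#' @param tolerance minimum distance-map depth (px) between two maxima for
#'   them to count as separate markers; 0.5 separates touching disks down
#'   to centre separations of 0.6 diameters without splitting single round
#'   nuclei.
#' @return integer-labelled matrix; the maximum label is the nucleus count.
#' @export
separateNuclei <- function(ki67Mask, expectedDiameterPx = 16, tolerance = 0.5) {
  if (!any(ki67Mask)) return(matrix(0L, nrow(ki67Mask), ncol(ki67Mask)))
  dm <- EBImage::distmap(EBImage::Image(ki67Mask * 1))
  ext <- max(1L, round(expectedDiameterPx / 4))
  lab <- EBImage::watershed(dm, tolerance = tolerance, ext = ext)
  matrix(as.integer(EBImage::imageData(lab)), nrow(ki67Mask), ncol(ki67Mask))
}

nucleusCentroids <- function(labels) {
  n <- max(labels)
  if (n == 0) return(matrix(numeric(0), 0, 2))
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  cx <- tapply(idx[, 1], lab, mean)
  cy <- tapply(idx[, 2], lab, mean)
  cbind(row = as.numeric(cx), col = as.numeric(cy))
}

#' Proliferating endothelial cell density
#'
#' A nucleus counts as a proliferating endothelial cell (PEC) when its
#' centroid falls within a vessel: the lectin mask with interior holes
#' filled, so nuclei enclosed by a vessel profile are captured
#' (`criterion = "centroid"`), or alternatively when at least half of its
#' pixels overlap the filled vessel mask (`criterion = "overlap"`).
#' Density is reported per mm^2 of (unfilled) lectin-positive vessel area.
#' Counts and areas are returned so per-tumor results can be pooled before
#' dividing.
#'
#' @param labels integer nucleus label matrix from [separateNuclei()].
#' @param masks a `StainMasks` list containing `lectin`.
#' @param umPerPx pixel size in micrometres.
#' @param criterion `"centroid"` (default) or `"overlap"`.
#' @return list of class `PECResult`: `nPec`, `nKi67Total`,
#'   `vesselAreaMm2`, `pecDensity` (per mm^2 of vessel; `NA` when the
#'   vessel area is zero).
#' @export
pecDensity <- function(labels, masks, umPerPx, criterion = c("centroid", "overlap")) {
  criterion <- match.arg(criterion)
  stopifnot(umPerPx > 0)
  vesselFilled <- matrix(
    as.logical(EBImage::imageData(EBImage::fillHull(EBImage::Image(masks$lectin * 1)))),
    nrow(masks$lectin), ncol(masks$lectin))
  nTotal <- max(labels)
  nPec <- 0L
  if (nTotal > 0) {
    if (criterion == "centroid") {
      cen <- round(nucleusCentroids(labels))
      cen[, 1] <- pmin(pmax(cen[, 1], 1), nrow(vesselFilled))
      cen[, 2] <- pmin(pmax(cen[, 2], 1), ncol(vesselFilled))
      nPec <- sum(vesselFilled[cen])
    } else {
      for (l in seq_len(nTotal)) {
        px <- labels == l
        if (sum(vesselFilled & px) >= 0.5 * sum(px)) nPec <- nPec + 1L
      }
    }
  }
  areaMm2 <- sum(masks$lectin) * (umPerPx / 1000)^2
  structure(list(
    nPec = as.integer(nPec), nKi67Total = as.integer(nTotal),
    vesselAreaMm2 = areaMm2,
    pecDensity = if (areaMm2 > 0) nPec / areaMm2 else NA_real_),
    class = "PECResult")
}

#' Pool per-field PEC results to a per-tumor density
#'
#' Counts and vessel areas are summed before dividing, so the pooled
#' density is invariant to how fields were partitioned.
#'
#' @param results list of `PECResult` objects.
#' @return a single pooled `PECResult`.
#' @export
poolPecResults <- function(results) {
  nPec <- sum(vapply(results, `[[`, integer(1), "nPec"))
  nTot <- sum(vapply(results, `[[`, integer(1), "nKi67Total"))
  area <- sum(vapply(results, `[[`, numeric(1), "vesselAreaMm2"))
  structure(list(nPec = nPec, nKi67Total = nTot, vesselAreaMm2 = area,
                 pecDensity = if (area > 0) nPec / area else NA_real_),
            class = "PECResult")
}

#' Immature (pericyte-negative) vessel area fraction
#'
#' For every connected lectin-positive component, the minimum Euclidean
#' distance to any alpha-SMA-positive pixel is computed (in micrometres).
#' Components at least `minDistUm` away (inclusive) are immature; the
#' immature fraction is their summed area over the total lectin-positive
#' area.  A per-pixel variant classifies individual lectin pixels instead
#' of whole components.
#'
#' @param masks a `StainMasks` list containing `lectin` and `sma`.
#' @param umPerPx pixel size in micrometres.
#' @param minDistUm distance threshold in micrometres (default 5).
#' @param perPixel if `TRUE`, apply the distance rule per lectin pixel
#'   instead of per connected vessel component.
#' @return list of class `MaturityResult`: `immatureAreaPx`,
#'   `totalLectinAreaPx`, `immatureFraction` (`NA` when there is no lectin
#'   area), and `immatureMask`.
#' @export
immatureVesselFraction <- function(masks, umPerPx, minDistUm = 5,
                                   perPixel = FALSE) {
  stopifnot(umPerPx > 0)
  lectin <- masks$lectin
  sma <- masks$sma
  total <- sum(lectin)
  if (total == 0) {
    return(structure(list(immatureAreaPx = 0L, totalLectinAreaPx = 0L,
                          immatureFraction = NA_real_,
                          immatureMask = lectin), class = "MaturityResult"))
  }
  if (!any(sma)) {
    distUm <- matrix(Inf, nrow(lectin), ncol(lectin))
  } else {
    distUm <- edtVoxels(sma)[, , 1] * umPerPx
  }
  if (perPixel) {
    immature <- lectin & distUm >= minDistUm
  } else {
    lab <- labelComponents(lectin)
    minDist <- tapply(distUm[lectin], lab[lectin], min)
    immatureLabels <- as.integer(names(minDist))[minDist >= minDistUm]
    immature <- lectin & array(lab %in% immatureLabels, dim(lab))
  }
  structure(list(
    immatureAreaPx = as.integer(sum(immature)),
    totalLectinAreaPx = as.integer(total),
    immatureFraction = sum(immature) / total,
    immatureMask = immature), class = "MaturityResult")
}

#' Quantify one histology field end to end
#'
#' Segments the stains, separates nuclei, and computes PEC density and (when
#' an alpha-SMA band is present and the mask is informative) the immature
#' vessel fraction.
#'
#' @param field a [StainField].
#' @param bands stain threshold bands.
#' @param expectedNucleusUm expected nucleus diameter in micrometres
#'   (watershed marker separation), default 8.
#' @return list with `masks`, `labels`, `pec`, `maturity`.
#' @export
quantifyField <- function(field, bands = defaultStainBands(),
                          expectedNucleusUm = 8) {
  masks <- segmentStains(field, bands)
  labels <- separateNuclei(masks$ki67,
                           expectedDiameterPx = expectedNucleusUm / field@umPerPx)
  pec <- pecDensity(labels, masks, field@umPerPx)
  maturity <- if (!is.null(masks$sma))
    immatureVesselFraction(masks, field@umPerPx) else NULL
  list(masks = masks, labels = labels, pec = pec, maturity = maturity)
}
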