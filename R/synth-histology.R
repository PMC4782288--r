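## Synthetic double-stained histology fields: blue tubular vessel profiles,
## brown elliptical nuclei (including touching pairs), and optional
## brick-red perivascular pericyte rims, painted with colors strictly inside
## the segmentation threshold bands and verified after 8-bit quantization.

# draw a filled disk into a logical matrix
diskMask <- function(shape, center, radius) {
  x0 <- max(1, floor(center[1] - radius)); x1 <- min(shape[1], ceiling(center[1] + radius))
  y0 <- max(1, floor(center[2] - radius)); y1 <- min(shape[2], ceiling(center[2] + radius))
  m <- array(FALSE, shape)
  if (x0 > x1 || y0 > y1) return(m)
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(xs - center[1], rep(1, length(ys)))
  dy <- outer(rep(1, length(xs)), ys - center[2])
  m[xs, ys] <- dx^2 + dy^2 <= radius^2
  m
}

# sample a stain color inside a band (with jitter), quantized to 8 bits
bandColor <- function(band, n = 1, jitter = TRUE) {
  mid <- function(r, frac = 0.25) {
    lo <- r[1] + frac * diff(r); hi <- r[2] - frac * diff(r)
    if (jitter) runif(n, lo, hi) else rep((lo + hi) / 2, n)
  }
  h <- mid(band$h); s <- mid(band$s)
  vr <- if (!is.null(band$v)) band$v else c(0.3, 0.9)
  v <- mid(vr)
  cols <- t(col2rgb(hsv(h, s, v))) / 255
  round(cols * 255) / 255
}

paintPixels <- function(img, mask, color) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- color[ch]
    img[, , ch] <- plane
  }
  img
}

#' Generate a double-stained histology field with exact ground truth
#'
#' Vessels are painted as blue capsule profiles, proliferating nuclei as
#' brown disks (a configurable fraction as touching pairs with centre
#' separation 0.6-0.9 diameters, guaranteeing watershed test cases), and,
#' when `withSma = TRUE`, pericyte coverage as brick-red rims around a
#' subset of vessels.  Rim-free vessels are farther than 5 um from any
#' pericyte pixel by construction (vessel placement enforces the
#' separation), so the immature ground truth is exact.  All painted colors
#' lie strictly inside the default hue/saturation bands; the generator
#' asserts that every painted pixel still classifies correctly after 8-bit
#' quantization.
#'
#' @param sizePx field dimensions in pixels.
#' @param umPerPx pixel size in micrometres (required; no magnification
#'   default is assumed).
#' @param nNuclei total nucleus count.
#' @param fracInVessel fraction of nuclei whose centroids lie inside a
#'   vessel profile (`round(fracInVessel * nNuclei)` nuclei, exactly).
#' @param withSma paint pericyte rims.
#' @param fracImmature target fraction of lectin area lacking pericyte
#'   coverage (subset of vessels chosen to approximate it); only used when
#'   `withSma = TRUE`.
#' @param nVessels number of vessel profiles.
#' @param vesselWidthUm vessel profile width in micrometres (default 30).
#' @param nucleusDiameterUm nucleus diameter in micrometres (default 8;
#'   must be at least 3 px at the chosen scale).
#' @param overlapPairFrac fraction of extravascular nuclei placed as
#'   touching pairs (default 0.2).
#' @param bands stain bands used for painting (default
#'   [defaultStainBands()]).
#' @param seed integer seed.
#' @return list with `field` (a [StainField]), ground-truth masks
#'   (`vesselMask`, `ki67Mask`, `smaMask`, `immatureMask`), `centers`
#'   (nucleus centres with an `inVessel` flag) and `truth`
#'   (`PhantomGroundTruth` with exact counts and areas).
#' @export
generateHistologyField <- function(sizePx = c(512, 512), umPerPx,
                                   nNuclei = 30, fracInVessel = 0.3,
                                   withSma = FALSE, fracImmature = 0.3,
                                   nVessels = 4, vesselWidthUm = 30,
                                   nucleusDiameterUm = 8,
                                   overlapPairFrac = 0.2,
                                   bands = defaultStainBands(), seed = NULL) {
  sizePx <- as.integer(sizePx)
  stopifnot(umPerPx > 0)
  rNuc <- nucleusDiameterUm / 2 / umPerPx
  if (2 * rNuc < 3) stop("nucleus diameter must be at least 3 px at this scale")
  halfWidth <- vesselWidthUm / 2 / umPerPx
  rimPx <- 3 / umPerPx                     # pericyte rim thickness ~3 um
  sepPx <- 5 / umPerPx                     # the maturity distance rule
  nInVessel <- round(fracInVessel * nNuclei)
  if (nInVessel > 0 && nVessels == 0)
    stop("invalid design: nuclei inside vessels require a non-zero vessel area")

  withSeed(seed, {
    # --- vessels: capsules with enforced pairwise separation ---------------
    segs <- list()
    tries <- 0
    # axis-to-axis clearance: pericyte fields need the 5 um maturity rule to
    # be unambiguous per vessel; proliferation fields only need distinct
    # vessel profiles
    minGap <- if (withSma) 2 * halfWidth + rimPx + sepPx + 4 else 2 * halfWidth + 4
    while (length(segs) < nVessels && tries < 4000) {
      tries <- tries + 1
      margin <- halfWidth + rimPx + 2
      p0 <- runif(2, margin, sizePx - margin)
      ang <- runif(1, 0, 2 * pi)
      len <- runif(1, 0.35, 0.6) * min(sizePx)
      p1 <- p0 + len * c(cos(ang), sin(ang))
      p1 <- pmin(pmax(p1, margin), sizePx - margin)
      ok <- TRUE
      for (s in segs) {
        dd <- min(segSegDistance(p0, p1, s$p0, s$p1),
                  segSegDistance(s$p0, s$p1, p0, p1))
        if (dd < minGap) { ok <- FALSE; break }
      }
      if (ok) segs[[length(segs) + 1]] <- list(p0 = p0, p1 = p1)
    }
    nVesselsPlaced <- length(segs)
    if (nInVessel > 0 && nVesselsPlaced == 0)
      stop("invalid design: no vessel could be placed for intravascular nuclei")
    vesselMasks <- lapply(segs, function(s)
      rasterizeCapsule2D(sizePx, s$p0, s$p1, halfWidth))
    vesselMask <- Reduce(`|`, vesselMasks, array(FALSE, sizePx))

    # --- pericyte rims: subset of vessels chosen to match fracImmature ----
    smaMask <- array(FALSE, sizePx)
    immatureIdx <- integer(0)
    if (withSma && nVesselsPlaced > 0) {
      areas <- vapply(vesselMasks, sum, numeric(1))
      immatureIdx <- chooseImmatureSubset(areas, fracImmature)
      for (i in setdiff(seq_len(nVesselsPlaced), immatureIdx)) {
        ring <- rasterizeCapsule2D(sizePx, segs[[i]]$p0, segs[[i]]$p1,
                                   halfWidth + rimPx) & !vesselMasks[[i]]
        smaMask <- smaMask | ring
      }
    }

    # --- nuclei ------------------------------------------------------------
    centers <- matrix(numeric(0), 0, 2)
    inVesselFlag <- logical(0)
    ki67Mask <- array(FALSE, sizePx)
    if (nNuclei > 0) {
      placeIn <- function() {
        # centre on a vessel axis so the disk is fully inside the profile;
        # the centre-gap constraint is relaxed progressively if needed
        for (gapFactor in c(2.2, 2.05, 1.9, 1.6, 1.3)) {
          for (it in 1:1500) {
            s <- segs[[sample.int(nVesselsPlaced, 1)]]
            t <- runif(1, 0.1, 0.9)
            cen <- s$p0 + t * (s$p1 - s$p0)
            if (all(cen > rNuc + 1) && all(cen < sizePx - rNuc - 1) &&
                (nrow(centers) == 0 ||
                 min(sqrt(rowSums(sweep(centers, 2, cen)^2))) > gapFactor * rNuc))
              return(cen)
          }
        }
        stop("could not place an intravascular nucleus")
      }
      distToVessels <- function(cen) {
        if (nVesselsPlaced == 0) return(Inf)
        min(vapply(segs, function(s) min(segSegDistance(cen, cen, s$p0, s$p1)),
                   numeric(1)))
      }
      placeOut <- function(minCentreGap = 2.2 * rNuc) {
        for (it in 1:2000) {
          cen <- runif(2, rNuc + 2, sizePx - rNuc - 2)
          if (distToVessels(cen) > halfWidth + rimPx + rNuc + 2 &&
              (nrow(centers) == 0 ||
               min(sqrt(rowSums(sweep(centers, 2, cen)^2))) > minCentreGap))
            return(cen)
        }
        stop("could not place an extravascular nucleus")
      }
      addNucleus <- function(cen, inside) {
        centers <<- rbind(centers, cen)
        inVesselFlag <<- c(inVesselFlag, inside)
        ki67Mask <<- ki67Mask | diskMask(sizePx, cen, rNuc)
      }
      for (i in seq_len(nInVessel)) addNucleus(placeIn(), TRUE)
      nOut <- nNuclei - nInVessel
      nPairs <- floor(overlapPairFrac * nOut / 2)
      for (i in seq_len(nPairs)) {
        cen <- placeOut(minCentreGap = 4 * rNuc)
        ang <- runif(1, 0, 2 * pi)
        sep <- runif(1, 0.6, 0.9) * 2 * rNuc
        addNucleus(cen, FALSE)
        addNucleus(cen + sep * c(cos(ang), sin(ang)), FALSE)
      }
      for (i in seq_len(nOut - 2 * nPairs)) addNucleus(placeOut(), FALSE)
    }

    # --- paint -------------------------------------------------------------
    img <- array(0.97, c(sizePx, 3L))        # near-white background
    img <- paintPixels(img, vesselMask, bandColor(bands$lectin))
    if (any(smaMask)) img <- paintPixels(img, smaMask, bandColor(bands$sma))
    if (any(ki67Mask)) img <- paintPixels(img, ki67Mask, bandColor(bands$ki67))

    # color-safety assertion after 8-bit quantization
    field <- StainField(img, umPerPx)
    masks <- segmentStains(field, bands)
    lectinFinal <- vesselMask & !ki67Mask & !smaMask
    smaFinal <- smaMask & !ki67Mask
    if (!identical(masks$lectin, lectinFinal) ||
        !identical(masks$ki67, ki67Mask) ||
        (!is.null(masks$sma) && !identical(masks$sma, smaFinal)))
      stop("internal error: painted colors left their threshold bands after quantization")

    immatureMask <- array(FALSE, sizePx)
    for (i in immatureIdx) immatureMask <- immatureMask | vesselMasks[[i]]
    immatureMask <- immatureMask & lectinFinal

    truth <- phantomTruth(
      nucleusCountInVessel = as.integer(nInVessel),
      nucleusCountTotal = as.integer(nNuclei),
      vesselAreaPx = as.integer(sum(lectinFinal)),
      immatureAreaPx = as.integer(sum(immatureMask)),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      nVessels = nVesselsPlaced)
    list(field = field, vesselMask = lectinFinal, ki67Mask = ki67Mask,
         smaMask = smaFinal, immatureMask = immatureMask,
         centers = if (nrow(centers)) data.frame(row = centers[, 1],
                                                 col = centers[, 2],
                                                 inVessel = inVesselFlag)
                   else data.frame(row = numeric(0), col = numeric(0),
                                   inVessel = logical(0)),
         truth = truth)
  })
}

# minimum distance between two 2D segments, approximated by dense sampling
segSegDistance <- function(a0, a1, b0, b1, n = 25) {
  ta <- seq(0, 1, length.out = n)
  pa <- cbind(a0[1] + ta * (a1[1] - a0[1]), a0[2] + ta * (a1[2] - a0[2]))
  d <- p2segDistance(pa, b0, b1)
  d
}

p2segDistance <- function(p, s0, s1) {
  d <- s1 - s0
  len2 <- sum(d^2)
  px <- p[, 1] - s0[1]; py <- p[, 2] - s0[2]
  if (len2 == 0) return(sqrt(px^2 + py^2))
  t <- pmin(1, pmax(0, (px * d[1] + py * d[2]) / len2))
  sqrt((px - t * d[1])^2 + (py - t * d[2])^2)
}

# choose the subset of vessel areas whose summed fraction is closest to the
# target immature fraction (exhaustive up to 12 vessels, greedy beyond)
chooseImmatureSubset <- function(areas, target) {
  n <- length(areas)
  total <- sum(areas)
  if (target <= 0) return(integer(0))
  if (n <= 12) {
    best <- integer(0); bestErr <- abs(target)
    for (m in 0:(2^n - 1)) {
      idx <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
      err <- abs(sum(areas[idx]) / total - target)
      if (err < bestErr) { best <- idx; bestErr <- err }
    }
    best
  } else {
    ord <- sample.int(n)
    acc <- 0; pick <- integer(0)
    for (i in ord) {
      if ((acc + areas[i]) / total <= target + 0.05) {
        pick <- c(pick, i); acc <- acc + areas[i]
      }
    }
    pick
  }
}
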