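## Semi-quantitative DCE-MRI perfusion analysis: voxel-wise relative
## enhancement maps, initial area under the enhancement curve over the first
## minute, the enhancing-voxel mask, and per-tumor summaries.

#' Compute voxel-wise enhancement maps from a dynamic series
#'
#' For each voxel, the pre-contrast baseline `S0` is the mean over all
#' pre-injection frames.  The relative signal intensity is
#' `RSI(t) = S(t) / S0`; `RSI_1min` is taken at the acquired frame nearest to
#' 60 s post-injection (no interpolation; at a 4.8 s frame interval 60 s
#' falls exactly between frames 12 and 13 post-injection and the later
#' frame, 62.4 s, is used).  `AUC_1min` is the trapezoidal integral of the
#' relative enhancement `(S(t) - S0) / S0` over the first 60 s post-injection,
#' with the injection instant anchored at the last baseline frame; when 60 s
#' is not an acquired time the final partial trapezoid uses the integrand's
#' native linear interpolation between the two bracketing frames.  Voxels
#' with `RSI_1min >= rsiThreshold` (default 1.5) within the ROI form the
#' enhancing mask; voxels with a non-positive baseline are flagged invalid
#' and excluded from the ROI.
#'
#' @param series a [DynamicSeries].
#' @param windowSeconds integration window after injection (default 60).
#' @param rsiThreshold enhancing-voxel threshold on `RSI_1min` (default 1.5;
#'   a voxel exactly at the threshold is enhancing).
#' @return a [PerfusionMaps].
#' @export
computeEnhancementMaps <- function(series, windowSeconds = 60,
                                   rsiThreshold = 1.5) {
  stopifnot(is(series, "DynamicSeries"))
  sig <- series@signal
  d <- dim(sig)
  nb <- series@baselineFrames
  dt <- series@frameInterval
  nFrames <- d[4]
  if (nb < 2)
    stop("at least two baseline frames are required")
  nPost <- nFrames - nb
  if (nPost * dt < windowSeconds)
    stop(sprintf("series too short: %.1f s post-injection available, %.1f s required",
                 nPost * dt, windowSeconds))

  dim(sig) <- c(prod(d[1:3]), nFrames)
  s0 <- rowMeans(sig[, seq_len(nb), drop = FALSE])
  valid <- as.vector(series@roi) & s0 > 0

  s0safe <- ifelse(s0 > 0, s0, NA_real_)

  # frame nearest to windowSeconds post-injection; ties go to the later frame
  jRsi <- floor(windowSeconds / dt + 0.5)
  rsi <- sig[, nb + jRsi] / s0safe

  # trapezoid over post-injection relative enhancement, tau = 0 at the last
  # baseline frame
  jMax <- floor(windowSeconds / dt)
  taus <- c(0, seq_len(jMax) * dt)
  frames <- nb + c(0, seq_len(jMax))
  enh <- sweep(sig[, frames, drop = FALSE], 1, s0safe, "/") - 1
  wts <- numeric(length(taus))
  for (k in seq_len(length(taus) - 1)) {
    h <- taus[k + 1] - taus[k]
    wts[k] <- wts[k] + h / 2
    wts[k + 1] <- wts[k + 1] + h / 2
  }
  auc <- as.numeric(enh %*% wts)
  if (jMax * dt < windowSeconds) {
    # partial trapezoid up to windowSeconds using the next acquired frame
    h <- windowSeconds - jMax * dt
    eLo <- enh[, jMax + 1]
    eNext <- sig[, nb + jMax + 1] / s0safe - 1
    eHi <- eLo + (eNext - eLo) * h / dt
    auc <- auc + h * (eLo + eHi) / 2
  }

  rsiMap <- array(ifelse(valid, rsi, 0), d[1:3])
  aucMap <- array(ifelse(valid, auc, 0), d[1:3])
  validRoi <- array(valid, d[1:3])
  enhancing <- validRoi & rsiMap >= rsiThreshold
  new("PerfusionMaps", rsi1min = rsiMap, auc1min = aucMap,
      baselineS0 = array(s0, d[1:3]), enhancingMask = enhancing,
      validRoi = validRoi, rsiThreshold = rsiThreshold)
}

#' Per-tumor perfusion summary
#'
#' The tumor-wise `AUC_1min` summary is the median over enhancing voxels
#' only (so that only perfused, viable tumor contributes); the fraction of
#' enhancing voxels (FEV) is the enhancing count over the ROI count.  With
#' no enhancing voxels the median is `NA` and FEV is 0.
#'
#' @param maps a [PerfusionMaps].
#' @param day imaging day label attached to the summary.
#' @param aucOverRoi if `TRUE`, compute the median AUC over all ROI voxels
#'   instead of enhancing voxels only.
#' @return a one-row data.frame with `day`, `medianAuc`, `fev`,
#'   `nEnhancing`, `nRoi`.
#' @export
summarizeTumor <- function(maps, day = NA_integer_, aucOverRoi = FALSE) {
  stopifnot(is(maps, "PerfusionMaps"))
  nRoi <- sum(maps@validRoi)
  if (nRoi == 0) stop("empty ROI")
  nEnh <- sum(maps@enhancingMask)
  sel <- if (aucOverRoi) maps@validRoi else maps@enhancingMask
  medAuc <- if (sum(sel) > 0) median(maps@auc1min[sel]) else NA_real_
  data.frame(day = day, medianAuc = medAuc, fev = nEnh / nRoi,
             nEnhancing = nEnh, nRoi = nRoi)
}

#' Longitudinal changes between consecutive imaging days
#'
#' Given per-tumor summaries ordered by day, computes the change in
#' `medianAuc` and `fev` over each consecutive day interval.
#'
#' @param summaries a data.frame of per-tumor summaries (rows as returned by
#'   [summarizeTumor()], one per day) with a `day` column; or a list of such
#'   rows.
#' @return data.frame with `interval` (e.g. "0-4"), `dayFrom`, `dayTo`,
#'   `deltaMedianAuc`, `deltaFev`; zero rows if fewer than two timepoints.
#' @export
longitudinalDelta <- function(summaries) {
  if (is.list(summaries) && !is.data.frame(summaries))
    summaries <- do.call(rbind, summaries)
  summaries <- summaries[order(summaries$day), , drop = FALSE]
  n <- nrow(summaries)
  if (n < 2) {
    warning("fewer than two timepoints: no intervals computed")
    return(data.frame(interval = character(), dayFrom = integer(),
                      dayTo = integer(), deltaMedianAuc = numeric(),
                      deltaFev = numeric()))
  }
  idx <- seq_len(n - 1)
  data.frame(
    interval = paste0(summaries$day[idx], "-", summaries$day[idx + 1]),
    dayFrom = summaries$day[idx],
    dayTo = summaries$day[idx + 1],
    deltaMedianAuc = summaries$medianAuc[idx + 1] - summaries$medianAuc[idx],
    deltaFev = summaries$fev[idx + 1] - summaries$fev[idx])
}
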