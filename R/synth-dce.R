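## Synthetic dynamic contrast-enhanced series with a designed enhancing
## fraction and saturating-exponential uptake.

#' Generate a DCE series phantom
#'
#' A designed subset of ROI voxels follows a monotone saturating-exponential
#' uptake `RSI(tau) = 1 + (peak - 1) * (1 - exp(-tau / tau0))` after the
#' injection (which occurs after the last baseline frame); the remaining
#' voxels stay flat at baseline.  Defaults mirror the emulated acquisition:
#' 200 frames at 4.8 s with injection after the tenth baseline image.
#'
#' @param shape spatial dimensions (x, y, slices).
#' @param nFrames number of frames (default 200).
#' @param frameInterval frame spacing in seconds (default 4.8).
#' @param baselineFrames pre-injection frames (default 10).
#' @param enhancingFraction designed fraction of ROI voxels that enhance,
#'   in `[0, 1]`.
#' @param peakEnhancement asymptotic relative signal intensity of enhancing
#'   voxels (default 2.5); values below 1.5 with a positive enhancing
#'   fraction trigger a warning because such voxels cannot pass the
#'   enhancing-voxel filter.
#' @param tau0 uptake time constant in seconds (default 12).
#' @param baselineSignal pre-contrast signal level (default 100).
#' @param noiseSd Gaussian noise SD as a fraction of the baseline signal
#'   (default 0).
#' @param seed integer seed.
#' @return list with `series` (a [DynamicSeries]), `enhancingMask` (designed
#'   logical 3D mask) and `truth` (`PhantomGroundTruth` with `trueFev` the
#'   exact designed enhancing-voxel fraction).
#' @export
generateDceSeries <- function(shape = c(32, 32, 4), nFrames = 200,
                              frameInterval = 4.8, baselineFrames = 10,
                              enhancingFraction = 0.4, peakEnhancement = 2.5,
                              tau0 = 12, baselineSignal = 100, noiseSd = 0,
                              seed = NULL) {
  shape <- as.integer(shape)
  stopifnot(baselineFrames >= 1, baselineFrames < nFrames,
            enhancingFraction >= 0, enhancingFraction <= 1)
  if (enhancingFraction > 0 && peakEnhancement < 1.5)
    warning("peak enhancement below 1.5: designed enhancing voxels will not pass the RSI filter")
  nVox <- prod(shape)
  nEnh <- round(enhancingFraction * nVox)

  withSeed(seed, {
    enhIdx <- if (nEnh > 0) sample.int(nVox, nEnh) else integer(0)
    enhMask <- array(FALSE, shape)
    enhMask[enhIdx] <- TRUE

    # time since injection per frame (0 for the baseline frames)
    tauPost <- c(rep(0, baselineFrames), seq_len(nFrames - baselineFrames)) *
      frameInterval
    rsi <- 1 + (peakEnhancement - 1) * (1 - exp(-tauPost / tau0))
    rsi[seq_len(baselineFrames)] <- 1

    sig <- array(baselineSignal, c(shape, nFrames))
    dim(sig) <- c(nVox, nFrames)
    if (nEnh > 0)
      sig[enhIdx, ] <- baselineSignal * matrix(rsi, nEnh, nFrames, byrow = TRUE)
    if (noiseSd > 0)
      sig <- sig + matrix(rnorm(nVox * nFrames, 0, noiseSd * baselineSignal),
                          nVox, nFrames)
    sig[sig < 0] <- 0
    dim(sig) <- c(shape, nFrames)

    truth <- phantomTruth(
      trueFev = nEnh / nVox,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
    list(series = DynamicSeries(sig, frameInterval, baselineFrames),
         enhancingMask = enhMask, truth = truth)
  })
}
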