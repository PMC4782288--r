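## 1D spectrum preprocessing: exponential line broadening (Lorentzian
## convolution), polynomial baseline correction, and mean normalization.

#' Apply exponential line broadening and baseline correction
#'
#' Line broadening by `lineBroadeningHz` is applied as convolution with a
#' normalized Lorentzian of that full width at half maximum, the frequency-
#' domain equivalent of exponential apodization of the FID; Lorentzian line
#' widths therefore add.  The ppm axis is converted to Hz with the
#' spectrometer frequency (default 600 MHz).  Optional baseline correction
#' fits a polynomial to the signal-free envelope (iterative clipping of
#' points above the fit) and subtracts it.
#'
#' @param spectra a [SpectrumSet] with a strictly monotone (descending) axis.
#' @param lineBroadeningHz Lorentzian FWHM to convolve with, in Hz
#'   (default 0.3); 0 is the identity.
#' @param spectrometerMHz spectrometer frequency in MHz used to convert ppm
#'   to Hz (default 600).
#' @param doBaseline apply polynomial baseline correction (default FALSE).
#' @param baselineOrder polynomial order for the baseline fit (default 3).
#' @return a [SpectrumSet] with processed intensities.
#' @export
preprocessSpectra <- function(spectra, lineBroadeningHz = 0.3,
                              spectrometerMHz = 600, doBaseline = FALSE,
                              baselineOrder = 3L) {
  stopifnot(is(spectra, "SpectrumSet"))
  ppm <- ppmAxis(spectra)
  if (length(ppm) > 1 && any(diff(ppm) >= 0))
    stop("ppm axis must be strictly monotone")
  x <- intensities(spectra)
  if (lineBroadeningHz > 0) {
    stepHz <- abs(ppm[1] - ppm[2]) * spectrometerMHz
    x <- t(apply(x, 1, lorentzianConvolve, stepHz = stepHz,
                 fwhmHz = lineBroadeningHz))
  }
  if (doBaseline) {
    x <- t(apply(x, 1, subtractBaseline, ppm = ppm, order = baselineOrder))
  }
  SpectrumSet(x, ppm, classLabels(spectra))
}

# Convolve one spectrum with a unit-area Lorentzian of FWHM fwhmHz sampled
# at stepHz; kernel truncated far into the tails, edges zero-padded.
lorentzianConvolve <- function(y, stepHz, fwhmHz) {
  gam <- fwhmHz / 2
  K <- max(5L, ceiling(200 * gam / stepHz))
  f <- seq(-K, K) * stepHz
  kern <- (gam / pi) / (f^2 + gam^2)
  kern <- kern / sum(kern)
  n <- length(y)
  ypad <- c(rep(0, K), y, rep(0, K))
  out <- stats::filter(ypad, kern, method = "convolution", sides = 2)
  as.numeric(out[(K + 1):(K + n)])
}

# Iterative polynomial baseline: fit, clip points above fit + small margin,
# refit; subtract the final fit.
subtractBaseline <- function(y, ppm, order = 3L, iterations = 10L) {
  keep <- rep(TRUE, length(y))
  X <- stats::poly(ppm, degree = order, raw = TRUE)
  fitVals <- rep(0, length(y))
  for (i in seq_len(iterations)) {
    fit <- lm.fit(cbind(1, X[keep, , drop = FALSE]), y[keep])
    fitVals <- cbind(1, X) %*% fit$coefficients
    resid <- y - fitVals
    s <- sd(resid[keep])
    keepNew <- resid < s
    if (identical(keepNew, keep)) break
    keep <- keepNew
    if (sum(keep) <= order + 1) break
  }
  as.numeric(y - fitVals)
}

#' Mean normalization
#'
#' Divides each spectrum by its mean intensity, removing sample-weight
#' scaling differences; every normalized spectrum has mean exactly 1.
#'
#' @param spectra a [SpectrumSet].
#' @return a [SpectrumSet] with unit-mean spectra.
#' @export
meanNormalize <- function(spectra) {
  stopifnot(is(spectra, "SpectrumSet"))
  x <- intensities(spectra)
  m <- rowMeans(x)
  if (any(m == 0)) stop("zero-mean spectrum cannot be normalized")
  SpectrumSet(x / m, ppmAxis(spectra), classLabels(spectra))
}

#' Restrict a spectrum set to a ppm window
#'
#' @param spectra a [SpectrumSet].
#' @param range length-2 ppm range (any order).
#' @return the cropped [SpectrumSet].
#' @export
cropPpm <- function(spectra, range) {
  stopifnot(is(spectra, "SpectrumSet"), length(range) == 2)
  lo <- min(range); hi <- max(range)
  keep <- ppmAxis(spectra) >= lo & ppmAxis(spectra) <= hi
  if (!any(keep)) stop("ppm window contains no points")
  SpectrumSet(intensities(spectra)[, keep, drop = FALSE],
              ppmAxis(spectra)[keep], classLabels(spectra))
}
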