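## Synthetic two-class HR MAS spectral cohorts: sums of Lorentzian lines on
## a smooth baseline with Gaussian noise; class effects act multiplicatively
## on designated peak amplitudes.

#' Default metabolite peak table
#'
#' Positions and widths of the main peaks emulated in the choline/creatine
#' region, with phosphocholine at 3.23 ppm and glycerophosphocholine at
#' 3.24 ppm (the two metabolites whose levels separate treated from control
#' tissue: PCho higher, GPC lower in treated samples).
#'
#' @return data.frame with `metabolite`, `ppm`, `fwhmHz`, `amplitude`.
#' @export
defaultPeakTable <- function() {
  data.frame(
    metabolite = c("Lac", "Ala", "Cr", "Cho", "PCho", "GPC", "Tau", "Gly", "Cr2"),
    ppm        = c(1.33, 1.47, 3.03, 3.21, 3.23, 3.24, 3.42, 3.55, 3.93),
    fwhmHz     = c(2.0, 1.5, 1.5, 1.5, 1.5, 1.5, 2.0, 1.5, 1.5),
    amplitude  = c(0.8, 0.3, 0.5, 0.4, 1.0, 1.0, 0.5, 0.4, 0.4))
}

lorentzianLine <- function(ppm, center, gammaPpm, amplitude) {
  amplitude * gammaPpm^2 / ((ppm - center)^2 + gammaPpm^2)
}

#' Generate a two-class cohort of synthetic spectra
#'
#' Each spectrum is a sum of Lorentzian lines plus a smooth baseline and
#' Gaussian noise.  Class effects multiply the designated peak amplitudes
#' in the treated class; biological variability multiplies every peak
#' amplitude by a per-sample log-normal factor.
#'
#' @param nPerClass samples per class; a single number or
#'   `c(control, treated)` (default 6 per class, the emulated group sizes).
#' @param ppm descending ppm axis (default 4.7 to 0.5 ppm in 0.001 ppm
#'   steps, a typical acquired resolution).
#' @param peaks peak table as from [defaultPeakTable()].
#' @param classEffects named multipliers applied to treated-class peak
#'   amplitudes (default `c(PCho = 1.5, GPC = 0.6)`); all 1 gives an
#'   exchangeable null design.
#' @param noiseSd Gaussian noise SD as a fraction of the largest base peak
#'   amplitude (default 0.01).
#' @param amplitudeCv per-sample log-normal coefficient of variation of
#'   peak amplitudes (default 0.05).
#' @param baselineAmplitude amplitude of the smooth polynomial baseline
#'   (default 0.05).
#' @param spectrometerMHz used to convert peak widths from Hz to ppm
#'   (default 600).
#' @param seed integer seed.
#' @return a [SpectrumSet] with labels `control`/`treated`.
#' @export
generateSpectraCohort <- function(nPerClass = 6,
                                  ppm = seq(4.7, 0.5, by = -0.001),
                                  peaks = defaultPeakTable(),
                                  classEffects = c(PCho = 1.5, GPC = 0.6),
                                  noiseSd = 0.01, amplitudeCv = 0.05,
                                  baselineAmplitude = 0.05,
                                  spectrometerMHz = 600, seed = NULL) {
  if (length(nPerClass) == 1) nPerClass <- rep(nPerClass, 2)
  stopifnot(all(nPerClass >= 1))
  if (any(classEffects <= 0)) stop("class effects must be positive")
  labels <- factor(rep(c("control", "treated"), nPerClass),
                   levels = c("control", "treated"))
  n <- sum(nPerClass)
  gammaPpm <- peaks$fwhmHz / 2 / spectrometerMHz

  withSeed(seed, {
    x <- matrix(0, n, length(ppm))
    base <- baselineAmplitude *
      (0.5 + 0.3 * (ppm - min(ppm)) / diff(range(ppm)) +
       0.2 * ((ppm - mean(ppm)) / diff(range(ppm)))^2)
    for (i in seq_len(n)) {
      amps <- peaks$amplitude *
        exp(rnorm(nrow(peaks), 0, amplitudeCv))
      if (labels[i] == "treated" && length(classEffects)) {
        m <- match(names(classEffects), peaks$metabolite)
        ok <- !is.na(m)
        amps[m[ok]] <- amps[m[ok]] * classEffects[ok]
      }
      spec <- base
      for (k in seq_len(nrow(peaks)))
        spec <- spec + lorentzianLine(ppm, peaks$ppm[k], gammaPpm[k], amps[k])
      if (noiseSd > 0)
        spec <- spec + rnorm(length(ppm), 0, noiseSd * max(peaks$amplitude))
      x[i, ] <- spec
    }
    colnames(x) <- formatC(ppm, format = "f", digits = 4)
    rownames(x) <- paste0(labels, "_", unlist(lapply(nPerClass, seq_len)))
    SpectrumSet(x, ppm, labels)
  })
}
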