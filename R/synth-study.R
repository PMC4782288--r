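## Two-arm synthetic study generator: per-tumor phantoms for every modality
## in control and treated arms, with treated-arm parameters scaled by the
## designed effect sizes.

#' Describe a two-arm study design
#'
#' Defaults mirror the emulated study: six tumors per arm (the molecular
#' cohort size), imaging on days 0, 4 and 7, and treated-arm effects in the
#' reported directions — lower vessel volume fraction, fewer immature
#' vessels, a perfusion decline between days 4 and 7, higher phosphocholine
#' and lower glycerophosphocholine.  Setting every effect to 1 yields an
#' exchangeable null design.
#'
#' @param nControl,nTreated tumors per arm (>= 1).
#' @param timepoints imaging days.
#' @param effectSizes named multiplicative treated-vs-control effects:
#'   `fbv`, `immature`, `aucDay4` (treated uptake scaling on intermediate
#'   days — the transient early increase), `aucDay7` (final-day uptake
#'   scaling), `fevDay7`, `pcho`, `gpc`.  All must be positive; 1 means no
#'   effect.
#' @param noiseLevels named noise levels: `microct` (grayscale SD),
#'   `dce` (fraction of baseline signal), `spectra` (fraction of the
#'   largest peak).
#' @return list of class `StudyDesign`.
#' @export
studyDesign <- function(nControl = 6, nTreated = 6, timepoints = c(0, 4, 7),
                        effectSizes = c(fbv = 0.73, immature = 0.71,
                                        aucDay4 = 1.1, aucDay7 = 0.7,
                                        fevDay7 = 0.85,
                                        pcho = 1.5, gpc = 0.6),
                        noiseLevels = c(microct = 0.02, dce = 0.01,
                                        spectra = 0.01)) {
  stopifnot(nControl >= 1, nTreated >= 1)
  if (any(effectSizes <= 0)) stop("effect sizes must be positive")
  defaults <- c(fbv = 1, immature = 1, aucDay4 = 1, aucDay7 = 1,
                fevDay7 = 1, pcho = 1, gpc = 1)
  defaults[names(effectSizes)] <- effectSizes
  structure(list(nControl = as.integer(nControl),
                 nTreated = as.integer(nTreated),
                 timepoints = timepoints, effectSizes = defaults,
                 noiseLevels = noiseLevels), class = "StudyDesign")
}

#' Generate a complete two-arm synthetic study
#'
#' For each tumor: a micro-CT phantom grown to the arm's target vessel
#' volume fraction, a dynamic series per imaging day (treated tumors show a
#' mild uptake increase on day 4 and the designed decline on the final
#' day), a proliferation-stained field and a pericyte-stained field; plus
#' one spectral cohort across both arms.  A manifest records every
#' component with its ground truth; regenerating with the same seed gives
#' an identical study.
#'
#' @param design a [studyDesign()].
#' @param seed integer seed for the whole study.
#' @param microctShape,dceShape phantom dimensions.
#' @param controlFbv control-arm target vessel volume fraction
#'   (default 0.059, a typical untreated value).
#' @param controlImmature control-arm immature vessel area fraction target
#'   (default 0.30).
#' @param controlPeak control-arm asymptotic relative enhancement
#'   (default 2.5).
#' @param enhancingFraction designed enhancing-voxel fraction (default 0.4).
#' @param umPerPxKi67,umPerPxSma pixel sizes of the two stained fields
#'   (defaults 0.5 and 1.0 um/px for the high- and low-magnification
#'   acquisitions).
#' @param writeDir optional directory; when given, volumes, series, fields,
#'   spectra and a JSON manifest are written there.
#' @return list of class `VascStudy` with `design`, `seed`, `arms`
#'   (per-tumor component lists), `spectra` and `manifest`.
#' @export
generateTwoGroupStudy <- function(design = studyDesign(), seed = 1,
                                  microctShape = c(64, 64, 64),
                                  dceShape = c(24, 24, 4),
                                  controlFbv = 0.059,
                                  controlImmature = 0.30,
                                  controlPeak = 2.5,
                                  enhancingFraction = 0.4,
                                  umPerPxKi67 = 0.5, umPerPxSma = 1.0,
                                  writeDir = NULL) {
  stopifnot(inherits(design, "StudyDesign"))
  eff <- design$effectSizes
  nz <- design$noiseLevels
  arms <- list(control = vector("list", design$nControl),
               treated = vector("list", design$nTreated))
  seedBase <- as.integer(seed) %% 100000L

  dayPeak <- function(arm, day) {
    last <- max(design$timepoints)
    if (arm == "control") return(controlPeak)
    if (day == last) return(1 + (controlPeak - 1) * eff[["aucDay7"]])
    mid <- setdiff(design$timepoints, range(design$timepoints))
    if (day %in% mid) return(1 + (controlPeak - 1) * eff[["aucDay4"]])
    controlPeak
  }
  dayFrac <- function(arm, day) {
    if (arm == "treated" && day == max(design$timepoints))
      return(enhancingFraction * eff[["fevDay7"]])
    enhancingFraction
  }

  for (arm in names(arms)) {
    nArm <- if (arm == "control") design$nControl else design$nTreated
    fbvTarget <- if (arm == "control") controlFbv else controlFbv * eff[["fbv"]]
    immTarget <- if (arm == "control") controlImmature
                 else controlImmature * eff[["immature"]]
    for (i in seq_len(nArm)) {
      tumorSeed <- seedBase + 1000L * match(arm, names(arms)) + i
      micro <- generateVascularPhantom(
        shape = microctShape, targetFbv = fbvTarget,
        noiseSd = nz[["microct"]], seed = tumorSeed)
      dce <- lapply(design$timepoints, function(day) {
        generateDceSeries(
          shape = dceShape, enhancingFraction = dayFrac(arm, day),
          peakEnhancement = dayPeak(arm, day), noiseSd = nz[["dce"]],
          seed = tumorSeed + 17L * (day + 1L))
      })
      names(dce) <- as.character(design$timepoints)
      histKi67 <- generateHistologyField(
        sizePx = c(384, 384), umPerPx = umPerPxKi67, nNuclei = 30,
        fracInVessel = 0.25, withSma = FALSE, nVessels = 3,
        seed = tumorSeed + 7001L)
      histSma <- generateHistologyField(
        sizePx = c(384, 384), umPerPx = umPerPxSma, nNuclei = 0,
        fracInVessel = 0, withSma = TRUE, fracImmature = immTarget,
        nVessels = 6, seed = tumorSeed + 7013L)
      arms[[arm]][[i]] <- list(
        id = sprintf("%s_%02d", arm, i),
        microct = micro, dce = dce,
        histKi67 = histKi67, histSma = histSma)
    }
  }

  spectra <- generateSpectraCohort(
    nPerClass = c(design$nControl, design$nTreated),
    classEffects = c(PCho = eff[["pcho"]], GPC = eff[["gpc"]]),
    noiseSd = nz[["spectra"]], seed = seedBase + 90001L)

  manifest <- studyManifest(design, seed, arms)
  study <- structure(list(design = design, seed = as.integer(seed),
                          arms = arms, spectra = spectra,
                          manifest = manifest), class = "VascStudy")
  if (!is.null(writeDir)) writeStudy(study, writeDir)
  study
}

studyManifest <- function(design, seed, arms) {
  rows <- list()
  for (arm in names(arms)) {
    for (t in arms[[arm]]) {
      rows[[length(rows) + 1]] <- data.frame(
        id = t$id, group = arm,
        trueFbv = t$microct$truth$trueFbv,
        trueFevDay0 = t$dce[[1]]$truth$trueFev,
        vesselAreaPx = t$histKi67$truth$vesselAreaPx,
        immatureAreaPx = t$histSma$truth$immatureAreaPx,
        lectinAreaSmaField = t$histSma$truth$vesselAreaPx)
    }
  }
  list(seed = as.integer(seed),
       timepoints = design$timepoints,
       effectSizes = as.list(design$effectSizes),
       noiseLevels = as.list(design$noiseLevels),
       tumors = do.call(rbind, rows))
}
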