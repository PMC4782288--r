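## End-to-end study pipeline: run every modality's stage on every tumor,
## compare arms with the nonparametric layer, and assemble a study report.

#' Default pipeline configuration
#'
#' All thresholds surface here with the values the analysis chain defaults
#' to: the 1.5 relative-signal enhancing-voxel cut, the 150 um large-vessel
#' and 200 um avascular-distance cuts, the 5 um pericyte distance rule, and
#' alpha = 0.05.
#'
#' @param vesselScalesUm vesselness scales (um).
#' @param rsiThreshold enhancing-voxel threshold.
#' @param vcCutUm,dnvCutUm caliber and distance cut-offs (um).
#' @param maturityDistUm pericyte distance rule (um).
#' @param alpha significance level.
#' @param plsComponents,plsRegionPpm,plsPermutations chemometrics settings.
#' @param lineBroadeningHz spectral apodization width.
#' @return list of class `studyConfig`.
#' @export
studyConfig <- function(vesselScalesUm = c(9, 18, 36, 72),
                        rsiThreshold = 1.5, vcCutUm = 150, dnvCutUm = 200,
                        maturityDistUm = 5, alpha = 0.05,
                        plsComponents = 2L, plsRegionPpm = c(3.0, 3.5),
                        plsPermutations = 1000L, lineBroadeningHz = 0.3) {
  structure(as.list(environment()), class = "studyConfig")
}

#' Run a full two-arm study through every analysis stage
#'
#' Per tumor: micro-CT morphometry (vesselness segmentation, FBV, caliber
#' and distance metrics), per-day perfusion summaries with consecutive-day
#' changes, and histology quantification (PEC density, immature vessel
#' fraction).  Per metric: a two-tailed Mann-Whitney comparison of arms
#' with median +/- MAD summaries.  The spectral cohort is line-broadened,
#' mean-normalized, cropped to the analysis window and classified by
#' PLS-DA with an optional permutation test.  Tumors whose stage fails are
#' excluded with a logged reason.
#'
#' @param study a `VascStudy` from [generateTwoGroupStudy()] (or a
#'   compatible list built from files).
#' @param config a [studyConfig()].
#' @param doPermutation run the PLS-DA permutation test (default TRUE).
#' @return list of class `StudyReport`: `comparisons` (one row per metric),
#'   `perTumor`, `plsda`, `histograms` (pooled caliber/distance
#'   histograms), `exclusions`, `provenance`.
#' @export
runStudy <- function(study, config = studyConfig(), doPermutation = TRUE) {
  stopifnot(inherits(study, "VascStudy"))
  exclusions <- list()
  perTumor <- list()
  days <- study$design$timepoints
  lastInterval <- paste0(days[length(days) - 1], "-", days[length(days)])

  for (arm in names(study$arms)) {
    for (tumor in study$arms[[arm]]) {
      row <- list(id = tumor$id, group = arm)
      ok <- tryCatch({
        morpho <- microctMorphometry(tumor$microct$volume,
                                     scales = config$vesselScalesUm)
        row$fbv <- morpho$fbv
        if (!is.null(morpho$caliber)) {
          row$vcP90 <- morpho$caliber$vcP90
          row$fracVcGt150 <- morpho$caliber$fracVcGtCut
          row$vcHist <- list(morpho$caliber$histogram)
        }
        if (!is.null(morpho$dnv)) {
          row$dnvMedian <- morpho$dnv$dnvMedian
          row$dnvP90 <- morpho$dnv$dnvP90
          row$fracDnvGt200 <- morpho$dnv$fracDnvGtCut
          row$dnvHist <- list(morpho$dnv$histogram)
        }

        summaries <- do.call(rbind, lapply(names(tumor$dce), function(day) {
          maps <- computeEnhancementMaps(tumor$dce[[day]]$series,
                                         rsiThreshold = config$rsiThreshold)
          summarizeTumor(maps, day = as.numeric(day))
        }))
        deltas <- longitudinalDelta(summaries)
        for (d in seq_len(nrow(summaries))) {
          row[[paste0("medianAuc_day", summaries$day[d])]] <- summaries$medianAuc[d]
          row[[paste0("fev_day", summaries$day[d])]] <- summaries$fev[d]
        }
        for (d in seq_len(nrow(deltas))) {
          iv <- gsub("-", "_", deltas$interval[d])   # syntactic column names
          row[[paste0("deltaAuc_", iv)]] <- deltas$deltaMedianAuc[d]
          row[[paste0("deltaFev_", iv)]] <- deltas$deltaFev[d]
        }

        ki67 <- quantifyField(tumor$histKi67$field)
        row$pecDensity <- ki67$pec$pecDensity
        smaMasks <- segmentStains(tumor$histSma$field)
        mat <- immatureVesselFraction(smaMasks, tumor$histSma$field@umPerPx,
                                      minDistUm = config$maturityDistUm)
        row$immatureFraction <- mat$immatureFraction
        TRUE
      }, error = function(e) {
        exclusions[[tumor$id]] <<- conditionMessage(e)
        FALSE
      })
      if (ok) perTumor[[tumor$id]] <- row
    }
  }

  if (length(perTumor) == 0) stop("every tumor failed its analysis stage")
  perTumorDf <- do.call(rbind, lapply(perTumor, function(r) {
    as.data.frame(r[setdiff(names(r), c("vcHist", "dnvHist"))])
  }))
  rownames(perTumorDf) <- NULL

  metricCols <- setdiff(names(perTumorDf), c("id", "group"))
  comparisons <- do.call(rbind, lapply(metricCols, function(m) {
    a <- perTumorDf[[m]][perTumorDf$group == "control"]
    b <- perTumorDf[[m]][perTumorDf$group == "treated"]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 1 || length(b) < 1) return(NULL)
    cmp <- mannWhitneyU(a, b, metric = m, alpha = config$alpha)
    data.frame(metric = m,
               medianControl = cmp@medianA, madControl = cmp@madA,
               medianTreated = cmp@medianB, madTreated = cmp@madB,
               U = cmp@uStatistic, p = cmp@pValue, method = cmp@method,
               nControl = length(a), nTreated = length(b),
               significant = cmp@pValue < config$alpha)
  }))
  rownames(comparisons) <- NULL

  spectra <- meanNormalize(preprocessSpectra(
    study$spectra, lineBroadeningHz = config$lineBroadeningHz))
  plsSet <- cropPpm(spectra, config$plsRegionPpm)
  model <- fitPLSDA(plsSet, ncomp = config$plsComponents)
  perm <- if (doPermutation)
    plsdaPermutationTest(plsSet, ncomp = config$plsComponents,
                         nPermutations = config$plsPermutations,
                         seed = study$seed + 555L)
  else NULL

  structure(list(
    comparisons = comparisons,
    perTumor = perTumorDf,
    plsda = list(model = model, permutation = perm,
                 region = config$plsRegionPpm),
    histograms = pooledHistograms(perTumor, perTumorDf),
    exclusions = exclusions,
    provenance = list(config = config, seed = study$seed,
                      package = as.character(utils::packageVersion("xenovasc")),
                      effectSizes = as.list(study$design$effectSizes))),
    class = "StudyReport")
}

# per-group median (and MAD) density per histogram bin, on each tumor's own
# normalized histogram resampled to shared breaks
pooledHistograms <- function(perTumor, perTumorDf) {
  pool <- function(key) {
    hl <- lapply(perTumor, function(r) if (!is.null(r[[key]])) r[[key]][[1]])
    keep <- !vapply(hl, is.null, logical(1))
    if (!any(keep)) return(NULL)
    groups <- perTumorDf$group[keep]
    hl <- hl[keep]
    mids <- sort(unique(unlist(lapply(hl, `[[`, "mid"))))
    dens <- vapply(hl, function(h) {
      d <- numeric(length(mids))
      d[match(h$mid, mids)] <- h$density
      d
    }, numeric(length(mids)))
    out <- do.call(rbind, lapply(unique(groups), function(g) {
      dg <- dens[, groups == g, drop = FALSE]
      data.frame(group = g, mid = mids,
                 density = apply(dg, 1, median),
                 mad = apply(dg, 1, function(x) median(abs(x - median(x)))))
    }))
    out
  }
  list(vc = pool("vcHist"), dnv = pool("dnvHist"))
}

#' @export
print.StudyReport <- function(x, ...) {
  cat("StudyReport:", nrow(x$perTumor), "tumors,",
      nrow(x$comparisons), "metric comparisons\n")
  sig <- x$comparisons[x$comparisons$significant, "metric"]
  cat("significant metrics:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  if (!is.null(x$plsda$permutation))
    cat(sprintf("PLS-DA: LOO accuracy %.2f, permutation p = %.4g\n",
                x$plsda$permutation$observedStat,
                x$plsda$permutation$pValue))
  invisible(x)
}
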