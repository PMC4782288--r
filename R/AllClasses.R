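## S4 carriers for the imaging, histology and spectroscopy data flowing
## through the pipeline.  Constructors validate physical metadata (voxel
## sizes, frame timing, axis monotonicity) so downstream metric code can
## assume well-formed inputs.

#' VolumeImage: a 3D scalar field with physical voxel size
#'
#' Carrier for micro-CT volumes and their tumor masks. Voxels are stored as a
#' 3D array; `voxelSize` is the isotropic edge length in micrometres.
#' Anisotropic voxels are not supported.
#'
#' @slot voxels 3D numeric array of image intensities.
#' @slot voxelSize isotropic voxel edge length in micrometres.
#' @slot tumorMask 3D logical array delimiting the tumor region.
#'
#' @param voxels,voxelSize,tumorMask see slots.
#' @param x a `VolumeImage` object.
#' @return `VolumeImage()` returns a validated object; `voxelSize()` and
#'   `tumorMask()` return the corresponding slots.
#' @examples
#' v <- VolumeImage(array(0, c(8, 8, 8)), voxelSize = 9)
#' voxelSize(v)
#' @export VolumeImage
#' @exportClass VolumeImage
#' @aliases VolumeImage
setClass("VolumeImage",
  representation(voxels = "array", voxelSize = "numeric", tumorMask = "array"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@voxels)) != 3L)
      msg <- c(msg, "voxels must be a 3D array")
    if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
        object@voxelSize <= 0)
      msg <- c(msg, "voxelSize must be a single positive number (micrometres)")
    if (!identical(dim(object@tumorMask), dim(object@voxels)))
      msg <- c(msg, "tumorMask must match the voxel array dimensions")
    if (!is.logical(object@tumorMask))
      msg <- c(msg, "tumorMask must be logical")
    if (length(msg)) msg else TRUE
  }
)

VolumeImage <- function(voxels, voxelSize, tumorMask = NULL) {
  if (is.null(tumorMask))
    tumorMask <- array(TRUE, dim(voxels))
  new("VolumeImage", voxels = voxels, voxelSize = as.numeric(voxelSize),
      tumorMask = tumorMask)
}

#' @rdname VolumeImage-class
setMethod("voxelSize", "VolumeImage", function(x) x@voxelSize)
#' @rdname VolumeImage-class
setMethod("tumorMask", "VolumeImage", function(x) x@tumorMask)

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("VolumeImage: %d x %d x %d voxels at %.3g um (tumor voxels: %d)\n",
              d[1], d[2], d[3], object@voxelSize, sum(object@tumorMask)))
})

#' DynamicSeries: a 4D dynamic contrast-enhanced acquisition
#'
#' Signal is stored as a 4D array (x, y, slice, frame). `baselineFrames` is
#' the number of pre-injection frames: the contrast bolus arrives after frame
#' `baselineFrames` (the acquisition geometry places the injection after the
#' tenth baseline image at a 4.8 s frame interval).
#'
#' @slot signal 4D numeric array (x, y, slice, frame), non-negative.
#' @slot frameInterval time between frames in seconds.
#' @slot baselineFrames number of pre-injection frames (>= 1).
#' @slot roi 3D logical tumor mask matching the spatial dimensions.
#'
#' @param signal,frameInterval,baselineFrames,roi see slots.
#' @param x a `DynamicSeries`.
#' @export DynamicSeries
#' @exportClass DynamicSeries
#' @aliases DynamicSeries
setClass("DynamicSeries",
  representation(signal = "array", frameInterval = "numeric",
                 baselineFrames = "integer", roi = "array"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@signal)) != 4L)
      msg <- c(msg, "signal must be a 4D array (x, y, slice, frame)")
    if (object@frameInterval <= 0)
      msg <- c(msg, "frameInterval must be positive")
    if (object@baselineFrames < 1L)
      msg <- c(msg, "baselineFrames must be >= 1")
    if (object@baselineFrames >= dim(object@signal)[4])
      msg <- c(msg, "baselineFrames must be smaller than the number of frames")
    if (!identical(dim(object@roi), dim(object@signal)[1:3]))
      msg <- c(msg, "roi must match the spatial dimensions of signal")
    if (any(object@signal < 0))
      msg <- c(msg, "signal must be non-negative")
    if (length(msg)) msg else TRUE
  }
)

DynamicSeries <- function(signal, frameInterval, baselineFrames, roi = NULL) {
  if (is.null(roi))
    roi <- array(TRUE, dim(signal)[1:3])
  new("DynamicSeries", signal = signal, frameInterval = as.numeric(frameInterval),
      baselineFrames = as.integer(baselineFrames), roi = roi)
}

#' @rdname DynamicSeries-class
setMethod("roi", "DynamicSeries", function(x) x@roi)
#' @rdname DynamicSeries-class
setMethod("frameInterval", "DynamicSeries", function(x) x@frameInterval)
#' @rdname DynamicSeries-class
setMethod("baselineFrames", "DynamicSeries", function(x) x@baselineFrames)

setMethod("show", "DynamicSeries", function(object) {
  d <- dim(object@signal)
  cat(sprintf(
    "DynamicSeries: %d x %d x %d voxels, %d frames at %.3g s (%d baseline)\n",
    d[1], d[2], d[3], d[4], object@frameInterval, object@baselineFrames))
})

#' StainField: an RGB histology field with physical pixel size
#'
#' The image is stored with channel values in `[0, 1]` quantized to 8 bits
#' (multiples of 1/255). `umPerPx` gives the pixel edge length in
#' micrometres at the acquisition magnification.
#'
#' @slot rgb numeric array (rows x cols x 3) in `[0, 1]`.
#' @slot umPerPx pixel edge length in micrometres.
#' @slot magnification free-text magnification tag (e.g. "10x", "40x").
#'
#' @param rgb,umPerPx,magnification see slots.
#' @export StainField
#' @exportClass StainField
#' @aliases StainField
setClass("StainField",
  representation(rgb = "array", umPerPx = "numeric", magnification = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@rgb)
    if (length(d) != 3L || d[3] != 3L)
      msg <- c(msg, "rgb must be a rows x cols x 3 array")
    if (any(object@rgb < 0 | object@rgb > 1))
      msg <- c(msg, "rgb values must lie in [0, 1]")
    if (object@umPerPx <= 0)
      msg <- c(msg, "umPerPx must be positive")
    if (length(msg)) msg else TRUE
  }
)

StainField <- function(rgb, umPerPx, magnification = "") {
  new("StainField", rgb = rgb, umPerPx = as.numeric(umPerPx),
      magnification = as.character(magnification))
}

setMethod("show", "StainField", function(object) {
  d <- dim(object@rgb)
  cat(sprintf("StainField: %d x %d px at %.3g um/px (%s)\n",
              d[1], d[2], object@umPerPx,
              if (nzchar(object@magnification)) object@magnification else "unknown mag"))
})

#' SpectrumSet: 1D spectra on a shared ppm axis with class labels
#'
#' Rows are samples, columns are ppm points; the ppm axis is stored in
#' descending order (NMR plotting convention).
#'
#' @slot intensities samples x points numeric matrix.
#' @slot ppm descending ppm axis, one value per column.
#' @slot labels factor of class labels (control/treated), one per row.
#'
#' @param intensities,ppm,labels see slots.
#' @param x a `SpectrumSet`.
#' @export SpectrumSet
#' @exportClass SpectrumSet
#' @aliases SpectrumSet
setClass("SpectrumSet",
  representation(intensities = "matrix", ppm = "numeric", labels = "factor"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@intensities) != length(object@ppm))
      msg <- c(msg, "ppm axis length must equal the number of columns")
    if (nrow(object@intensities) != length(object@labels))
      msg <- c(msg, "one class label per spectrum is required")
    if (length(object@ppm) > 1 && any(diff(object@ppm) >= 0))
      msg <- c(msg, "ppm axis must be strictly descending")
    if (length(msg)) msg else TRUE
  }
)

SpectrumSet <- function(intensities, ppm, labels) {
  new("SpectrumSet", intensities = as.matrix(intensities),
      ppm = as.numeric(ppm), labels = as.factor(labels))
}

#' @rdname SpectrumSet-class
setMethod("ppmAxis", "SpectrumSet", function(x) x@ppm)
#' @rdname SpectrumSet-class
setMethod("classLabels", "SpectrumSet", function(x) x@labels)
#' @rdname SpectrumSet-class
setMethod("intensities", "SpectrumSet", function(x) x@intensities)

setMethod("show", "SpectrumSet", function(object) {
  cat(sprintf("SpectrumSet: %d spectra x %d points, ppm %.3f..%.3f\n",
              nrow(object@intensities), ncol(object@intensities),
              object@ppm[1], object@ppm[length(object@ppm)]))
  print(table(object@labels))
})

#' VesselSegmentation: multiscale vesselness response and binary vessel mask
#'
#' @slot vesselness 3D array of the tubularity response rescaled to `[0, 1]`.
#' @slot vesselMask 3D logical vessel mask (subset of the tumor mask).
#' @slot scales analysis scales in micrometres.
#' @slot threshold the vesselness threshold used for the mask.
#' @slot voxelSize voxel edge length in micrometres.
#'
#' @param x a `VesselSegmentation`.
#' @export
#' @exportClass VesselSegmentation
setClass("VesselSegmentation",
  representation(vesselness = "array", vesselMask = "array",
                 scales = "numeric", threshold = "numeric",
                 voxelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@vesselness), dim(object@vesselMask)))
      msg <- c(msg, "vesselness and vesselMask dimensions must match")
    if (any(!is.finite(object@vesselness)))
      msg <- c(msg, "vesselness must be finite")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname VesselSegmentation-class
setMethod("vesselMask", "VesselSegmentation", function(x) x@vesselMask)
#' @rdname VesselSegmentation-class
setMethod("vesselness", "VesselSegmentation", function(x) x@vesselness)

setMethod("show", "VesselSegmentation", function(object) {
  cat(sprintf(
    "VesselSegmentation: %d vessel voxels, scales {%s} um, threshold %.4g\n",
    sum(object@vesselMask), paste(object@scales, collapse = ", "),
    object@threshold))
})

#' PerfusionMaps: voxel-wise semi-quantitative DCE-MRI maps
#'
#' Holds the pre-contrast baseline `S0`, the relative signal intensity about
#' one minute post-injection (`rsi1min`), the initial area under the relative
#' enhancement curve over the first minute (`auc1min`,
#' relative-enhancement x seconds), and the enhancing-voxel mask
#' (`RSI >= 1.5` within the valid ROI).
#'
#' @slot rsi1min,auc1min,baselineS0 3D numeric maps.
#' @slot enhancingMask 3D logical; enhancing voxels within the ROI.
#' @slot validRoi 3D logical; ROI voxels with a usable (positive) baseline.
#' @slot rsiThreshold the enhancing-voxel threshold applied (default 1.5).
#'
#' @param x a `PerfusionMaps`.
#' @export
#' @exportClass PerfusionMaps
setClass("PerfusionMaps",
  representation(rsi1min = "array", auc1min = "array", baselineS0 = "array",
                 enhancingMask = "array", validRoi = "array",
                 rsiThreshold = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@rsi1min), dim(object@auc1min)))
      msg <- c(msg, "map dimensions must agree")
    if (any(object@enhancingMask & !object@validRoi))
      msg <- c(msg, "enhancing mask must be a subset of the valid ROI")
    if (any(object@rsi1min[object@validRoi] < 0))
      msg <- c(msg, "RSI must be non-negative inside the ROI")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "PerfusionMaps", function(object) {
  cat(sprintf(
    "PerfusionMaps: %d ROI voxels, %d enhancing (RSI >= %.2g)\n",
    sum(object@validRoi), sum(object@enhancingMask), object@rsiThreshold))
})

#' @rdname PerfusionMaps-class
setMethod("enhancingMask", "PerfusionMaps", function(x) x@enhancingMask)

#' PLSDAModel: a two-class PLS-DA fit with VIP scores and cross-validation
#'
#' Latent variables are extracted by NIPALS PLS1 regression of the centred
#' spectral matrix on a +/-1 class response. `vipScores()` returns variable
#' importance on projection; the mean squared VIP over variables is 1 by
#' construction.
#'
#' @slot ncomp number of latent variables.
#' @slot scores samples x LV score matrix.
#' @slot loadings variables x LV loading matrix.
#' @slot weights variables x LV weight matrix (unit norm per LV).
#' @slot yLoadings response loadings per LV.
#' @slot ssy response sum of squares explained per LV.
#' @slot vip per-variable VIP scores.
#' @slot cvPredicted factor of leave-one-out class predictions.
#' @slot cvSensitivity,cvSpecificity leave-one-out performance (treated =
#'   positive class).
#' @slot labels observed class factor.
#' @slot varNames variable (ppm point) names.
#'
#' @param object a `PLSDAModel`.
#' @export
#' @exportClass PLSDAModel
setClass("PLSDAModel",
  representation(ncomp = "integer", scores = "matrix", loadings = "matrix",
                 weights = "matrix", yLoadings = "numeric", ssy = "numeric",
                 vip = "numeric", cvPredicted = "factor",
                 cvSensitivity = "numeric", cvSpecificity = "numeric",
                 labels = "factor", varNames = "character"))

#' @rdname PLSDAModel-class
setMethod("vipScores", "PLSDAModel", function(object) object@vip)

setMethod("show", "PLSDAModel", function(object) {
  cat(sprintf(
    "PLSDAModel: %d LVs, %d samples x %d variables\nLOO sensitivity %.3f, specificity %.3f\n",
    object@ncomp, nrow(object@scores), nrow(object@loadings),
    object@cvSensitivity, object@cvSpecificity))
})

#' GroupComparison: a two-group nonparametric comparison
#'
#' Wraps a two-tailed Mann-Whitney U test together with median +/- MAD
#' summaries of both groups (MAD unscaled, i.e. the median absolute
#' deviation as printed, with no consistency factor).
#'
#' @slot metric name of the compared quantity.
#' @slot groupA,groupB the raw per-tumor values.
#' @slot uStatistic the U statistic of group A.
#' @slot pValue two-tailed p value.
#' @slot method "exact" (full enumeration) or "normal-approximation".
#' @slot medianA,madA,medianB,madB group summaries.
#' @slot alpha significance threshold carried for reporting (0.05).
#'
#' @param object a `GroupComparison`.
#' @export
#' @exportClass GroupComparison
setClass("GroupComparison",
  representation(metric = "character", groupA = "numeric", groupB = "numeric",
                 uStatistic = "numeric", pValue = "numeric", method = "character",
                 medianA = "numeric", madA = "numeric", medianB = "numeric",
                 madB = "numeric", alpha = "numeric"),
  validity = function(object) {
    msg <- character()
    nab <- length(object@groupA) * length(object@groupB)
    if (object@uStatistic < 0 || object@uStatistic > nab)
      msg <- c(msg, "U must lie in [0, nA * nB]")
    if (object@pValue <= 0 || object@pValue > 1)
      msg <- c(msg, "p must lie in (0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname GroupComparison-class
setMethod("pValue", "GroupComparison", function(object) object@pValue)
#' @rdname GroupComparison-class
setMethod("uStatistic", "GroupComparison", function(object) object@uStatistic)

setMethod("show", "GroupComparison", function(object) {
  star <- if (object@pValue < object@alpha) " *" else ""
  cat(sprintf(
    "GroupComparison [%s]: %.4g +/- %.4g (n=%d) vs %.4g +/- %.4g (n=%d)\nU = %g, two-tailed p = %.4g (%s)%s\n",
    object@metric, object@medianA, object@madA, length(object@groupA),
    object@medianB, object@madB, length(object@groupB),
    object@uStatistic, object@pValue, object@method, star))
})
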