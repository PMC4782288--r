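#' @rdname VolumeImage-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname VolumeImage-class
#' @export
setGeneric("tumorMask", function(x) standardGeneric("tumorMask"))

#' @rdname VesselSegmentation-class
#' @export
setGeneric("vesselMask", function(x) standardGeneric("vesselMask"))

#' @rdname VesselSegmentation-class
#' @export
setGeneric("vesselness", function(x) standardGeneric("vesselness"))

#' @rdname DynamicSeries-class
#' @export
setGeneric("roi", function(x) standardGeneric("roi"))

#' @rdname DynamicSeries-class
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname DynamicSeries-class
#' @export
setGeneric("baselineFrames", function(x) standardGeneric("baselineFrames"))

#' @rdname PerfusionMaps-class
#' @export
setGeneric("enhancingMask", function(x) standardGeneric("enhancingMask"))

#' @rdname SpectrumSet-class
#' @export
setGeneric("ppmAxis", function(x) standardGeneric("ppmAxis"))

#' @rdname SpectrumSet-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname SpectrumSet-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname PLSDAModel-class
#' @export
setGeneric("vipScores", function(object) standardGeneric("vipScores"))

#' @rdname GroupComparison-class
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname GroupComparison-class
#' @export
setGeneric("uStatistic", function(object) standardGeneric("uStatistic"))
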