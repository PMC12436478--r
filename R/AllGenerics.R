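#' @rdname EchoSequence-class
#' @param object,x an object.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname LabelMaskSequence-class
#' @export
setGeneric("masks", function(x) standardGeneric("masks"))

#' @rdname EchoSequence-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname EchoSequence-class
#' @export
setGeneric("rPeakIndex", function(x) standardGeneric("rPeakIndex"))

#' @rdname StrainCurve-class
#' @export
setGeneric("strainValues", function(x) standardGeneric("strainValues"))

#' @rdname StrainCurve-class
#' @export
setGeneric("baseIndex", function(x) standardGeneric("baseIndex"))

#' Peak strain of a strain curve
#'
#' The peak strain is the maximum strain across all timestamps.
#'
#' @param x a [StrainCurve-class] or a numeric vector of strain values.
#' @return a single numeric, the maximum strain.
#' @examples
#' peakStrain(c(0, 0.10, 0.05))   # 0.10
#' @export
setGeneric("peakStrain", function(x) standardGeneric("peakStrain"))
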