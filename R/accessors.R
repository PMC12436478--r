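#' @rdname EchoSequence-class
#' @export
setMethod("frames", "EchoSequence", function(x) x@frames)

#' @rdname EchoSequence-class
#' @export
setMethod("nFrames", "EchoSequence", function(x) length(x@frames))

#' @rdname LabelMaskSequence-class
#' @export
setMethod("nFrames", "LabelMaskSequence", function(x) length(x@masks))

#' @rdname EchoSequence-class
#' @export
setMethod("rPeakIndex", "EchoSequence", function(x) x@rPeakIndex)

#' @rdname LabelMaskSequence-class
#' @export
setMethod("masks", "LabelMaskSequence", function(x) x@masks)

#' @rdname StrainCurve-class
#' @export
setMethod("strainValues", "StrainCurve", function(x) x@values)

#' @rdname StrainCurve-class
#' @export
setMethod("baseIndex", "StrainCurve", function(x) x@baseIndex)

#' @rdname peakStrain
#' @export
setMethod("peakStrain", "StrainCurve", function(x) max(x@values))

#' @rdname peakStrain
#' @export
setMethod("peakStrain", "numeric", function(x) {
  if (length(x) < 1L) stop("empty strain curve")
  max(x)
})

setMethod("show", "EchoSequence", function(object) {
  d <- dim(object@frames[[1L]])
  cat(sprintf("EchoSequence '%s': %d frame(s) of %d x %d", object@id,
              length(object@frames), d[1], d[2]))
  if (!is.na(object@rPeakIndex))
    cat(sprintf(", R peak at frame %d", object@rPeakIndex))
  cat("\n")
})

setMethod("show", "LabelMaskSequence", function(object) {
  d <- dim(object@masks[[1L]])
  cav <- mean(vapply(object@masks, function(m) mean(m == 1L), numeric(1)))
  cat(sprintf("LabelMaskSequence: %d mask(s) of %d x %d (mean cavity fraction %.3f)\n",
              length(object@masks), d[1], d[2], cav))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: %d frames, peak true strain %.3f, wall %.1f px\n",
              length(object@scale), max(object@trueStrain), object@wallThickness))
})

setMethod("show", "StrainCurve", function(object) {
  cat(sprintf("StrainCurve: %d value(s)%s, base frame %d, peak %.4f\n",
              length(object@values),
              if (object@isResampled) " (resampled)" else "",
              object@baseIndex, max(object@values)))
})

setMethod("show", "SegModel", function(object) {
  np <- sum(vapply(object@params, length, numeric(1)))
  cat(sprintf("SegModel (%s): %s parameters, trained %d epoch(s), final loss %.4f\n",
              object@config$arch, format(np, big.mark = ","),
              length(object@lossLog),
              if (length(object@lossLog)) object@lossLog[length(object@lossLog)] else NA))
})

setMethod("show", "AhreClassifier", function(object) {
  cat(sprintf("AhreClassifier: threshold %s, depth %d, %d head(s), width %d, trained %d epoch(s)\n",
              object@config$threshold, object@config$depth, object@config$heads,
              object@config$width, length(object@lossLog)))
})
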