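#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib echostrain, .registration = TRUE
NULL

#' EchoSequence: a grayscale echocardiographic image stack
#'
#' In-memory representation of one apical four-chamber acquisition: a list of
#' 2-D grayscale frames with intensities in [0, 1], optionally carrying the
#' ECG R-peak frame index (the base timestamp for strain) and the pixel
#' spacing in mm/pixel.
#'
#' @slot frames list of numeric matrices (height x width), values in [0, 1].
#' @slot rPeakIndex integer(1) or NA; 1-based frame index of the ECG R peak.
#' @slot pixelSpacing numeric(1) or NA; mm per pixel.
#' @slot id character(1) sequence identifier.
#' @seealso [makePhantom()], [sequenceToStrain()]
#' @export
setClass("EchoSequence",
  representation(frames = "list", rPeakIndex = "integer",
                 pixelSpacing = "numeric", id = "character"),
  prototype(rPeakIndex = NA_integer_, pixelSpacing = NA_real_, id = "seq"))

setValidity("EchoSequence", function(object) {
  f <- object@frames
  if (length(f) < 1L) return("at least one frame is required")
  if (!all(vapply(f, is.matrix, logical(1)))) return("frames must be matrices")
  d <- dim(f[[1L]])
  if (!all(vapply(f, function(m) identical(dim(m), d), logical(1))))
    return("all frames must share one height/width")
  rng <- range(unlist(lapply(f, range)))
  if (rng[1] < 0 || rng[2] > 1) return("frame intensities must lie in [0, 1]")
  rp <- object@rPeakIndex
  if (!is.na(rp) && (rp < 1L || rp > length(f)))
    return("rPeakIndex out of range")
  TRUE
})

#' LabelMaskSequence: per-frame cavity/wall label masks
#'
#' Label images aligned 1:1 with an [EchoSequence-class]'s frames. Labels are
#' 0 = background, 1 = LA cavity, 2 = LA wall.
#'
#' @slot masks list of integer matrices with values in \{0, 1, 2\}.
#' @export
setClass("LabelMaskSequence", representation(masks = "list"))

setValidity("LabelMaskSequence", function(object) {
  m <- object@masks
  if (length(m) < 1L) return("at least one mask is required")
  if (!all(vapply(m, is.matrix, logical(1)))) return("masks must be matrices")
  d <- dim(m[[1L]])
  if (!all(vapply(m, function(x) identical(dim(x), d), logical(1))))
    return("all masks must share one height/width")
  lv <- unique(unlist(lapply(m, function(x) unique(as.vector(x)))))
  if (!all(lv %in% c(0L, 1L, 2L))) return("labels must be in {0, 1, 2}")
  TRUE
})

#' PhantomTruth: analytic ground truth of a synthetic phantom
#'
#' Carries the base-frame endocardial contour, the periodic scale function
#' applied per frame, and the resulting analytic strain, so that strain
#' extracted from rendered masks can be validated against an exact oracle.
#'
#' @slot baseContour two-column matrix (x, y) of sub-pixel vertex coordinates
#'   of the closed LA endocardial polyline at the base frame.
#' @slot scale numeric vector, per-frame scale factor s(t) (> 0, s = 1 at the
#'   base frame).
#' @slot trueStrain numeric vector, s(t) - 1.
#' @slot wallThickness numeric(1), wall thickness in pixels.
#' @slot sector named list of fan-geometry parameters (apex, span, radius).
#' @export
setClass("PhantomTruth",
  representation(baseContour = "matrix", scale = "numeric",
                 trueStrain = "numeric", wallThickness = "numeric",
                 sector = "list"))

setValidity("PhantomTruth", function(object) {
  if (any(object@scale <= 0)) return("scale factors must be positive")
  b <- which.min(abs(object@scale - 1))
  if (abs(object@scale[b] - 1) > 1e-12) return("scale must equal 1 at the base frame")
  if (max(abs(object@trueStrain - (object@scale - 1))) > 1e-12)
    return("trueStrain must equal scale - 1")
  TRUE
})

#' StrainCurve: fractional LA strain over a cardiac cycle
#'
#' Fractional strain per frame, `(L_t - L_0) / L_0`, relative to the contour
#' length at the base frame (the ECG R peak / LV end-diastole). A resampled
#' curve holds exactly 30 equidistantly sampled values.
#'
#' @slot values numeric vector of fractional strains.
#' @slot baseIndex integer(1), 1-based index of the base frame (within the
#'   original, pre-resampling frame sequence).
#' @slot isResampled logical(1); if TRUE, `values` has exactly 30 entries.
#' @export
setClass("StrainCurve",
  representation(values = "numeric", baseIndex = "integer",
                 isResampled = "logical"),
  prototype(isResampled = FALSE))

setValidity("StrainCurve", function(object) {
  if (length(object@values) < 1L) return("empty strain curve")
  if (object@isResampled && length(object@values) != 30L)
    return("a resampled strain curve must hold exactly 30 values")
  if (!object@isResampled) {
    if (object@baseIndex < 1L || object@baseIndex > length(object@values))
      return("baseIndex out of range")
    if (abs(object@values[object@baseIndex]) > 1e-12)
      return("strain at the base frame must be 0")
  }
  TRUE
})

#' SegModel: a trained multi-class segmentation network
#'
#' Opaque container for a trained encoder-decoder segmenter: the weights, the
#' architecture graph metadata, its configuration, and the per-epoch training
#' loss log.
#'
#' @slot params list of weight arrays.
#' @slot config the `segConfig()` list used for training.
#' @slot lossLog numeric vector of per-epoch mean training losses.
#' @export
setClass("SegModel",
  representation(params = "list", config = "list", lossLog = "numeric"))

#' AhreClassifier: a trained transformer AHRE classifier
#'
#' Transformer encoder over the 30-point strain curve with a learned summary
#' token carrying the ten clinical features; sigmoid output head. Stores the
#' training-set standardization constants for the numeric features and for
#' the strain tokens.
#'
#' @slot params list of weight matrices.
#' @slot config the `clfConfig()` list used for training.
#' @slot featCenter,featScale numeric(10) standardization constants for the
#'   clinical features.
#' @slot strainCenter,strainScale numeric(30) per-timestamp standardization
#'   constants for the strain curve.
#' @slot lossLog numeric vector of per-epoch training losses.
#' @export
setClass("AhreClassifier",
  representation(params = "list", config = "list",
                 featCenter = "numeric", featScale = "numeric",
                 strainCenter = "numeric", strainScale = "numeric",
                 lossLog = "numeric"))
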