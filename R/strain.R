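## Contour-length based LA strain.
##
## The endocardial length -- the contour length of the segmented cavity -- is
## the strain surrogate: strain_t = (L_t - L_0)/L_0 with L_0 measured at the
## base timestamp (the ECG R peak / LV end-diastole). Curves are resampled to
## 30 equidistant frames before classification.

#' Extract the sub-pixel endocardial contour from a label mask
#'
#' Takes the largest connected component of the cavity label, smooths the
#' binary field with a small Gaussian, and traces the 0.5 iso-contour
#' (marching squares). Smoothing removes the pixel-staircase bias that would
#' otherwise inflate the perimeter of a rasterized smooth shape by several
#' percent. By default the smoothing scale grows with the object's linear
#' size (`sqrt(area)/40`), which keeps the small residual length bias
#' scale-invariant so that it cancels in the strain ratio; a rasterized
#' circle of radius 50 px is recovered to well under 2% of 2*pi*r.
#'
#' @param maskFrame integer matrix with cavity pixels labelled
#'   `cavityLabel`.
#' @param cavityLabel label value of the cavity (default 1).
#' @param smoothSigma Gaussian sigma (pixels) applied to the binary cavity
#'   field before iso-contouring; `NULL` (default) uses the area-adaptive
#'   scale.
#' @return a two-column matrix of ordered (x = column, y = row) vertex
#'   coordinates of the closed contour (last vertex connects to the first).
#' @examples
#' m <- matrix(0L, 64, 64)
#' m[as.matrix(expand.grid(20:44, 20:44))] <- 1L
#' nrow(extractContour(m)) > 20
#' @export
extractContour <- function(maskFrame, cavityLabel = 1L, smoothSigma = NULL) {
  cav <- (maskFrame == cavityLabel) * 1
  if (sum(cav) == 0) stop("empty cavity")
  lab <- EBImage::bwlabel(cav)
  sizes <- tabulate(lab[lab > 0])
  cav <- (lab == which.max(sizes)) * 1
  sig <- if (is.null(smoothSigma)) sqrt(sum(cav)) / 40 else smoothSigma
  repeat {
    z <- if (sig > 0) EBImage::gblur(cav, sigma = sig) else cav
    cl <- grDevices::contourLines(seq_len(nrow(z)), seq_len(ncol(z)), z,
                                  levels = 0.5)
    if (length(cl) > 0) break
    sig <- sig / 2
    if (sig < 0.05) stop("empty cavity")  # component too small to contour
  }
  lens <- vapply(cl, function(cc) length(cc$x), numeric(1))
  cc <- cl[[which.max(lens)]]
  ## contourLines' x follows the first index (row), y the second (column)
  v <- cbind(x = cc$y, y = cc$x)
  if (nrow(v) > 1 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  v
}

#' Length of a closed polyline
#'
#' Sum of consecutive vertex distances including the closing segment back to
#' the first vertex.
#'
#' @param polyline two-column matrix of (x, y) vertices (>= 3 rows; a
#'   repeated final vertex equal to the first is tolerated).
#' @return total length (pixels).
#' @examples
#' contourLength(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))  # 4
#' @export
contourLength <- function(polyline) {
  v <- as.matrix(polyline)
  if (nrow(v) > 1 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3L) stop("a closed polyline needs at least 3 vertices")
  x <- v[, 1]; y <- v[, 2]
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

#' Select the base (zero-strain) frame
#'
#' Returns the ECG R-peak frame when available; otherwise the frame of
#' minimum contour length, since the LA is smallest at LV end-diastole. Ties
#' resolve to the earliest frame.
#'
#' @param lengths numeric vector of per-frame contour lengths.
#' @param rPeakIndex optional 1-based R-peak frame index.
#' @return 1-based base frame index.
#' @export
selectBaseFrame <- function(lengths, rPeakIndex = NULL) {
  if (length(lengths) < 1L) stop("no frames")
  if (!is.null(rPeakIndex) && !is.na(rPeakIndex)) {
    rPeakIndex <- as.integer(rPeakIndex)
    if (rPeakIndex < 1L || rPeakIndex > length(lengths))
      stop("rPeakIndex out of range")
    return(rPeakIndex)
  }
  which.min(lengths)
}

#' Strain curve from per-frame contour lengths
#'
#' Fractional strain `(L_t - L_0)/L_0` relative to the base-frame length.
#'
#' @param lengths per-frame contour lengths (all > 0).
#' @param baseIndex 1-based base frame index.
#' @return a [StrainCurve-class].
#' @examples
#' strainValues(strainCurve(c(100, 110, 105), 1))  # 0, 0.10, 0.05
#' @export
strainCurve <- function(lengths, baseIndex = 1L) {
  baseIndex <- as.integer(baseIndex)
  if (baseIndex < 1L || baseIndex > length(lengths)) stop("baseIndex out of range")
  L0 <- lengths[baseIndex]
  if (!is.finite(L0) || L0 <= 0) stop("base contour length must be positive")
  if (any(lengths <= 0)) stop("all contour lengths must be positive")
  v <- (lengths - L0) / L0
  v[baseIndex] <- 0
  new("StrainCurve", values = v, baseIndex = baseIndex, isResampled = FALSE)
}

#' Equidistant resampling of a strain curve to 30 frames
#'
#' Frame counts vary between acquisitions; classification inputs are
#' standardized to `m = 30` frames by equidistant index sampling
#' `round(i * (T - 1)/(m - 1))`, always retaining the first and last frame.
#' Sequences shorter than `m` frames are rejected.
#'
#' @param curve a [StrainCurve-class] or numeric vector.
#' @param m target number of samples (default 30).
#' @return same type as the input, with exactly `m` values.
#' @export
resampleEquidistant <- function(curve, m = 30L) {
  vals <- if (is(curve, "StrainCurve")) curve@values else as.numeric(curve)
  Tn <- length(vals)
  m <- as.integer(m)
  if (Tn < m) stop("insufficient frames: ", Tn, " < ", m)
  idx <- floor(seq(0L, m - 1L) * (Tn - 1) / (m - 1) + 0.5) + 1L
  out <- vals[idx]
  if (is(curve, "StrainCurve"))
    new("StrainCurve", values = out, baseIndex = curve@baseIndex,
        isResampled = m == 30L)
  else out
}

#' Strain curve of a whole mask sequence
#'
#' Composition of the full strain chain: per-frame contour extraction and
#' length, base-frame selection, the strain formula, and (optionally)
#' 30-point equidistant resampling.
#'
#' @param maskSeq a [LabelMaskSequence-class] (every frame must contain
#'   cavity pixels) or a list of label matrices.
#' @param rPeakIndex optional R-peak frame index; when absent the
#'   minimum-length frame is the base.
#' @param resample resample to 30 values (default TRUE).
#' @param medianFilter apply a 3-frame running median to the lengths before
#'   computing strain (off by default).
#' @return a [StrainCurve-class].
#' @export
sequenceToStrain <- function(maskSeq, rPeakIndex = NULL, resample = TRUE,
                             medianFilter = FALSE) {
  ms <- if (is(maskSeq, "LabelMaskSequence")) maskSeq@masks else maskSeq
  lengths <- vapply(seq_along(ms), function(t) {
    v <- tryCatch(extractContour(ms[[t]]),
                  error = function(e) stop("frame ", t, ": ", conditionMessage(e),
                                           call. = FALSE))
    contourLength(v)
  }, numeric(1))
  if (medianFilter && length(lengths) >= 3L)
    lengths <- stats::runmed(lengths, 3L)
  b <- selectBaseFrame(lengths, rPeakIndex)
  sc <- strainCurve(lengths, b)
  if (resample) resampleEquidistant(sc, 30L) else sc
}
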