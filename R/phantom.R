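## Synthetic apical four-chamber phantoms.
##
## The left atrium is drawn as a truncated superellipse whose closed
## endocardial polyline is scaled isotropically about its own centroid by a
## per-frame factor s(t), so the contour length scales exactly by s(t) and the
## fractional strain (L_t - L_0)/L_0 equals s(t) - 1 analytically. Everything
## else in the scene (fan sector, speckle, an LV-like chamber above the LA)
## exists to make segmentation and quality control non-trivial.

#' Phantom generation parameters
#'
#' Geometry, cycle and noise settings for [makePhantom()]. All linear
#' quantities marked `Frac` are fractions of the image height/width so the
#' scene scales with `size`.
#'
#' @param size image side length in pixels (square frames).
#' @param nframes number of frames T in the sequence.
#' @param wallThickness LA wall thickness in pixels (>= 1).
#' @param sMax peak contour scale factor; peak true strain is `sMax - 1`.
#' @param speckleSd multiplicative speckle strength on tissue (exponential
#'   noise is scaled towards 1 by this mixing weight; 0 = none).
#' @param blurSigma Gaussian point-spread blur in pixels.
#' @param sectorSpan full fan opening angle, degrees.
#' @param sectorRadiusFrac fan radius as a fraction of image height.
#' @param laCenterFrac,laAxesFrac LA centre (x, y) and semi-axes (a, b) as
#'   fractions of width/height.
#' @param laExponent superellipse exponent (2 = ellipse; larger = boxier).
#' @param laTruncFrac the LA outline is cut flat (the mitral-annulus side) at
#'   `laTruncFrac * b` above the centre.
#' @param renderLv render the LV-like second chamber above the LA.
#' @param tissueI,wallI,cavityI base intensities of myocardial tissue, the LA
#'   wall and blood pools (the LV pool always renders at blood-pool
#'   darkness).
#' @return a named list of parameters.
#' @export
phantomParams <- function(size = 224L, nframes = 40L, wallThickness = 3,
                          sMax = 1.25, speckleSd = 0.6, blurSigma = 0.8,
                          sectorSpan = 78, sectorRadiusFrac = 0.95,
                          laCenterFrac = c(0.52, 0.68),
                          laAxesFrac = c(0.16, 0.14),
                          laExponent = 2.5, laTruncFrac = 0.55,
                          renderLv = TRUE, tissueI = 0.55, wallI = 0.88,
                          cavityI = 0.05) {
  if (size < 16L || nframes < 1L) stop("non-positive or too small dimensions")
  if (sMax <= 1) stop("sMax must exceed 1")
  if (wallThickness < 1) stop("wall thickness must be at least 1 pixel")
  list(size = as.integer(size), nframes = as.integer(nframes),
       wallThickness = wallThickness, sMax = sMax, speckleSd = speckleSd,
       blurSigma = blurSigma, sectorSpan = sectorSpan,
       sectorRadiusFrac = sectorRadiusFrac, laCenterFrac = laCenterFrac,
       laAxesFrac = laAxesFrac, laExponent = laExponent,
       laTruncFrac = laTruncFrac, renderLv = renderLv,
       tissueI = tissueI, wallI = wallI, cavityI = cavityI)
}

## Closed truncated-superellipse polyline (x = col, y = row), ~nv vertices.
.laBaseContour <- function(p) {
  W <- p$size; H <- p$size
  cx <- p$laCenterFrac[1] * W; cy <- p$laCenterFrac[2] * H
  a <- p$laAxesFrac[1] * W; b <- p$laAxesFrac[2] * H
  n <- p$laExponent
  th <- seq(0, 2 * pi, length.out = 721L)[-721L]
  sx <- sign(cos(th)) * abs(cos(th))^(2 / n)
  sy <- sign(sin(th)) * abs(sin(th))^(2 / n)
  x <- cx + a * sx
  y <- cy + b * sy
  keep <- y >= cy - p$laTruncFrac * b           # cut the top (annulus plane) flat
  x <- x[keep]; y <- y[keep]
  ## reorder so the polyline runs continuously from one cut end to the other
  o <- order(atan2(y - cy, x - cx))
  x <- x[o]; y <- y[o]
  ## close across the flat top with a straight chord (few interpolated points)
  i1 <- which.min(y + 1e-6 * x); i2 <- which.min(y - 1e-6 * x)
  ends <- range(c(i1, i2))
  xs <- c(x[ends[2]:length(x)], x[1:ends[1]])
  ys <- c(y[ends[2]:length(y)], y[1:ends[1]])
  chord <- seq(0, 1, length.out = 12L)[c(-1L, -12L)]
  xs <- c(xs, xs[length(xs)] + chord * (xs[1] - xs[length(xs)]))
  ys <- c(ys, ys[length(ys)] + chord * (ys[1] - ys[length(ys)]))
  cbind(x = xs, y = ys)
}

.polyCentroid <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  c(sum((x + x2) * cr) / (6 * A), sum((y + y2) * cr) / (6 * A))
}

.polyLength <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

## Raised-cosine reservoir scale curve: s = 1 at frame 1 (the designated ECG
## R peak), exact peak sMax at the integer mid-sequence frame, back to 1.
.scaleCurve <- function(nframes, sMax) {
  if (nframes == 1L) return(1)
  m <- nframes %/% 2L + 1L
  t <- seq_len(nframes)
  s <- numeric(nframes)
  up <- t <= m
  s[up] <- 1 + (sMax - 1) * 0.5 * (1 - cos(pi * (t[up] - 1) / (m - 1)))
  s[!up] <- 1 + (sMax - 1) * 0.5 * (1 + cos(pi * (t[!up] - m) / (nframes - m)))
  s
}

.sectorMask <- function(p) {
  W <- p$size; H <- p$size
  apex <- c(W / 2, 4)
  r <- p$sectorRadiusFrac * H
  half <- p$sectorSpan / 2 * pi / 180
  xx <- matrix(rep(seq_len(W), each = H), H)
  yy <- matrix(rep(seq_len(H), W), H)
  dx <- xx - apex[1]; dy <- yy - apex[2]
  ang <- atan2(dx, dy)                      # 0 = straight down
  (dx^2 + dy^2 <= r^2) & (abs(ang) <= half) & (dy > 0)
}

.lvPolygon <- function(p) {
  W <- p$size; H <- p$size
  cx <- 0.46 * W; cy <- 0.32 * H
  a <- 0.15 * W; b <- 0.21 * H
  th <- seq(0, 2 * pi, length.out = 181L)[-181L]
  cbind(cx + a * cos(th), cy + b * sin(th))
}

## Render one frame given the scaled cavity polygon. Returns list(img, mask).
.renderFrame <- function(p, poly, sector, lvMask, noise) {
  H <- p$size; W <- p$size
  cavity <- fill_polygon_cpp(H, W, poly[, 1], poly[, 2]) == 1L
  brush <- EBImage::makeBrush(2L * ceiling(p$wallThickness) + 1L, shape = "disc")
  wall <- (EBImage::dilate(cavity * 1, brush) > 0.5) & !cavity
  img <- p$tissueI * noise$tissue
  img[wall] <- p$wallI * noise$tissue[wall]
  img[cavity] <- p$cavityI + noise$cavity[cavity]
  if (!is.null(lvMask)) {
    lvOnly <- lvMask & !wall & !cavity
    img[lvOnly] <- 0.05 + noise$cavity[lvOnly]
  }
  img[!sector] <- 0
  if (p$blurSigma > 0) img <- EBImage::gblur(img, sigma = p$blurSigma)
  img[!sector] <- 0
  img <- pmin(pmax(img, 0), 1)
  mask <- matrix(0L, H, W)
  mask[wall] <- 2L
  mask[cavity] <- 1L
  list(img = img, mask = mask)
}

#' Generate a synthetic apical four-chamber phantom sequence
#'
#' Renders a fan-shaped ultrasound sector containing a speckled two-chamber
#' scene: an LA (bright wall around a dark cavity, labelled) below an
#' unlabelled LV-like chamber. Across frames the LA endocardial polyline is
#' scaled isotropically about its centroid by a raised-cosine factor s(t), so
#' the true fractional strain is exactly s(t) - 1 and the returned
#' [PhantomTruth-class] is an analytic oracle for strain extraction. The R
#' peak is frame 1 (s = 1 there).
#'
#' @param params parameter list from [phantomParams()].
#' @param seed integer seed; identical params + seed give bit-identical
#'   output.
#' @param id sequence identifier.
#' @return a list with elements `sequence` ([EchoSequence-class]), `masks`
#'   ([LabelMaskSequence-class]) and `truth` ([PhantomTruth-class]).
#' @examples
#' ph <- makePhantom(phantomParams(size = 96, nframes = 8), seed = 1)
#' ph$truth
#' @export
makePhantom <- function(params = phantomParams(), seed = 1L, id = "phantom") {
  p <- params
  base <- .laBaseContour(p)
  ctr <- .polyCentroid(base)
  s <- .scaleCurve(p$nframes, p$sMax)
  sector <- .sectorMask(p)
  lvMask <- if (p$renderLv) {
    lv <- .lvPolygon(p)
    fill_polygon_cpp(p$size, p$size, lv[, 1], lv[, 2]) == 1L
  } else NULL
  old <- .Random.seed_exists()
  set.seed(seed)
  frames <- vector("list", p$nframes)
  msk <- vector("list", p$nframes)
  n <- p$size^2
  for (t in seq_len(p$nframes)) {
    noise <- list(
      tissue = matrix(1 - p$speckleSd + p$speckleSd * stats::rexp(n), p$size),
      cavity = matrix(stats::rnorm(n, 0, 0.02), p$size))
    poly <- cbind(ctr[1] + s[t] * (base[, 1] - ctr[1]),
                  ctr[2] + s[t] * (base[, 2] - ctr[2]))
    fr <- .renderFrame(p, poly, sector, lvMask, noise)
    frames[[t]] <- fr$img
    msk[[t]] <- fr$mask
  }
  .restoreSeed(old)
  list(
    sequence = new("EchoSequence", frames = frames, rPeakIndex = 1L,
                   pixelSpacing = NA_real_, id = id),
    masks = new("LabelMaskSequence", masks = msk),
    truth = new("PhantomTruth", baseContour = base, scale = s,
                trueStrain = s - 1, wallThickness = p$wallThickness,
                sector = list(apex = c(p$size / 2, 4),
                              spanDeg = p$sectorSpan,
                              radius = p$sectorRadiusFrac * p$size)))
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
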