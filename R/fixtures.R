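## Degenerate single-frame fixtures realizing each clean-subset exclusion
## criterion. Fixtures are constructed, not mined: each starts from a clean
## phantom frame and applies one targeted defect, carrying its kind as
## metadata so quality-control checks have labels.

#' Fixture kinds
#'
#' The five exclusion criteria for the clean segmentation subset:
#' \describe{
#'   \item{single_chamber (a)}{only one chamber visible (the LV is omitted).}
#'   \item{truncated_bottom (b)}{cavity mask clipped flat against the bottom
#'     image edge.}
#'   \item{beyond_sector (c)}{a material fraction of the mask lies outside
#'     the rendered echo sector.}
#'   \item{blurred_boundary (d)}{the LA boundary is low-contrast and
#'     heavily blurred.}
#'   \item{black_region (e)}{a significant dark blob sits inside the
#'     ground-truth mask, straddling cavity and wall.}
#' }
#' @export
fixtureKinds <- function() c("single_chamber", "truncated_bottom",
                             "beyond_sector", "blurred_boundary",
                             "black_region")

#' Generate a degenerate QC fixture
#'
#' Returns a single-frame sequence/mask pair violating exactly the named
#' exclusion criterion and none of the others.
#'
#' @param kind one of [fixtureKinds()] (letters a-e in the same order).
#' @param seed integer seed.
#' @param size image side length in pixels.
#' @return list with `sequence` ([EchoSequence-class]), `masks`
#'   ([LabelMaskSequence-class]) and `kind`.
#' @examples
#' fx <- makeFixture("black_region", seed = 3, size = 128)
#' fx$kind
#' @export
makeFixture <- function(kind = fixtureKinds(), seed = 1L, size = 224L) {
  kind <- match.arg(kind)
  base <- switch(kind,
    single_chamber = phantomParams(size = size, nframes = 1L, renderLv = FALSE),
    truncated_bottom = phantomParams(size = size, nframes = 1L,
                                     laCenterFrac = c(0.52, 0.97),
                                     sectorRadiusFrac = 1.35),
    blurred_boundary = phantomParams(size = size, nframes = 1L,
                                     wallI = 0.32, cavityI = 0.20,
                                     blurSigma = 3.0, speckleSd = 0.3),
    phantomParams(size = size, nframes = 1L))
  ph <- makePhantom(base, seed = seed, id = paste0("fixture_", kind))
  img <- ph$sequence@frames[[1L]]
  mask <- ph$masks@masks[[1L]]
  if (kind == "beyond_sector") {
    ## blank the image below the row where >= 8% of mask pixels remain,
    ## emulating a mask that extends past the echocardiographic area
    rowCounts <- rowSums(mask > 0)
    cum <- rev(cumsum(rev(rowCounts)))
    cut <- min(which(cum <= 0.08 * sum(mask > 0)))
    img[cut:nrow(img), ] <- 0
  } else if (kind == "black_region") {
    ## grow a dark disc centred on the lowest cavity-boundary point until it
    ## covers >= 11% of the cavity and >= 11% of the wall
    cav <- mask == 1L
    wal <- mask == 2L
    idx <- which(cav, arr.ind = TRUE)
    cy <- max(idx[, 1])
    cx <- round(mean(idx[idx[, 1] == cy, 2]))
    xx <- matrix(rep(seq_len(ncol(img)), each = nrow(img)), nrow(img))
    yy <- matrix(rep(seq_len(nrow(img)), ncol(img)), nrow(img))
    for (r in seq(10, size, by = 2)) {
      disc <- (xx - cx)^2 + (yy - cy)^2 <= r^2
      if (sum(disc & cav) >= 0.11 * sum(cav) && sum(disc & wal) >= 0.11 * sum(wal))
        break
    }
    img[disc] <- 0.02
  }
  list(sequence = new("EchoSequence", frames = list(img), rPeakIndex = 1L,
                      pixelSpacing = NA_real_, id = paste0("fixture_", kind)),
       masks = new("LabelMaskSequence", masks = list(mask)),
       kind = kind)
}
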