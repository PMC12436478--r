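## Clean-subset quality control.
##
## The original exclusion criteria were applied by visual review; here each
## one is encoded as a measurable proxy with stated, configurable defaults.
## QC applies to the segmentation training path only: strain extraction and
## classification consume complete frame sequences.

#' Estimated sector (echo-area) support of an image
#'
#' Pixels with appreciable signal after morphological closing, with enclosed
#' holes filled (the blood pools and any dark blob inside the fan count as
#' support; regions connected to the image border do not).
#'
#' @param image grayscale matrix in [0, 1].
#' @param level intensity floor defining signal support.
#' @return logical matrix.
#' @export
sectorSupport <- function(image, level = 0.02) {
  bin <- (image > level) * 1
  cl <- EBImage::closing(bin, EBImage::makeBrush(5L, shape = "disc"))
  EBImage::fillHull(cl) > 0.5
}

## mean image-gradient magnitude sampled along the cavity iso-contour
.boundaryGradient <- function(image, mask) {
  v <- extractContour(mask)
  H <- nrow(image); W <- ncol(image)
  gy <- (rbind(image[-1, , drop = FALSE], image[H, , drop = FALSE]) -
           rbind(image[1, , drop = FALSE], image[-H, , drop = FALSE])) / 2
  gx <- (cbind(image[, -1, drop = FALSE], image[, W, drop = FALSE]) -
           cbind(image[, 1, drop = FALSE], image[, -W, drop = FALSE])) / 2
  gm <- sqrt(gx^2 + gy^2)
  r <- pmin(pmax(v[, 2], 1), H)
  c <- pmin(pmax(v[, 1], 1), W)
  r0 <- pmin(floor(r), H - 1); c0 <- pmin(floor(c), W - 1)
  fr <- r - r0; fc <- c - c0
  g <- gm[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    gm[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    gm[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    gm[cbind(r0 + 1, c0 + 1)] * fr * fc
  mean(g)
}

#' Flag a: only a single chamber visible
#'
#' TRUE when no second dark-chamber candidate exists: a connected dark
#' region (intensity below `darkLevel`) inside the sector support, disjoint
#' from the LA mask, with area at least `minAreaFrac` of the cavity area.
#'
#' @param image,mask aligned grayscale image and label mask.
#' @param darkLevel intensity threshold for "dark".
#' @param minAreaFrac minimum candidate area as a fraction of cavity area.
#' @return logical flag.
#' @export
checkSingleChamber <- function(image, mask, darkLevel = 0.15,
                               minAreaFrac = 0.25) {
  if (sum(mask > 0) == 0) stop("empty mask")
  cavArea <- sum(mask == 1L)
  dark <- (image < darkLevel) & sectorSupport(image) & (mask == 0L)
  lab <- EBImage::bwlabel(dark * 1)
  if (max(lab) == 0) return(TRUE)
  sizes <- tabulate(lab[lab > 0])
  !any(sizes >= minAreaFrac * cavArea)
}

#' Flag b: mask truncated by the bottom image boundary
#'
#' TRUE when at least `minRun` consecutive mask (cavity or wall) pixels lie
#' on the last image row.
#'
#' @param mask label mask.
#' @param minRun minimum run length (default 20).
#' @return logical flag.
#' @export
checkTruncatedBottom <- function(mask, minRun = 20L) {
  bottom <- mask[nrow(mask), ] > 0L
  if (!any(bottom)) return(FALSE)
  r <- rle(bottom)
  any(r$lengths[r$values] >= minRun)
}

#' Flag c: mask extends beyond the echocardiographic area
#'
#' TRUE when the fraction of mask pixels outside the estimated sector
#' support reaches `threshold`.
#'
#' @inheritParams checkSingleChamber
#' @param threshold minimum outside-support fraction (default 0.02).
#' @return logical flag.
#' @export
checkBeyondSector <- function(image, mask, threshold = 0.02) {
  if (all(image == 0)) stop("empty image")
  m <- mask > 0L
  if (sum(m) == 0) stop("empty mask")
  sum(m & !sectorSupport(image)) / sum(m) >= threshold
}

#' Flag d: blurred LA boundary
#'
#' TRUE when the mean image-gradient magnitude sampled along the cavity
#' iso-contour falls below `factor` times a reference gradient. Inside
#' [applyExclusions()] the reference is the dataset median; standalone, the
#' default reference corresponds to a sharp-walled phantom boundary.
#'
#' @inheritParams checkSingleChamber
#' @param refGradient reference boundary gradient (intensity units/pixel).
#' @param factor calibrated fraction of the reference (default 0.5).
#' @return logical flag.
#' @export
checkBlurredBoundary <- function(image, mask, refGradient = 0.15,
                                 factor = 0.5) {
  .boundaryGradient(image, mask) < factor * refGradient
}

#' Flag e: significant black region within the mask
#'
#' TRUE when dark pixels (below `darkLevel`, inside the sector support)
#' cover at least `threshold` of the wall label, or when the cavity label
#' splits into a main component plus dark secondary blobs of comparable
#' total area. A uniformly dark cavity alone is normal blood pool and does
#' not raise the flag.
#'
#' @inheritParams checkSingleChamber
#' @param darkLevel intensity threshold for "black" (default 0.05).
#' @param threshold minimum dark fraction (default 0.10).
#' @return logical flag.
#' @export
checkBlackRegion <- function(image, mask, darkLevel = 0.05, threshold = 0.10) {
  if (sum(mask > 0) == 0) stop("empty mask")
  dark <- (image < darkLevel) & sectorSupport(image)
  wall <- mask == 2L
  if (sum(wall) > 0 && sum(dark & wall) / sum(wall) >= threshold) return(TRUE)
  lab <- EBImage::bwlabel((mask == 1L) * 1)
  if (max(lab) > 1) {
    sizes <- tabulate(lab[lab > 0])
    main <- which.max(sizes)
    sec <- which(seq_along(sizes) != main & sizes >= threshold * sizes[main])
    for (s in sec)
      if (mean(image[lab == s]) < darkLevel) return(TRUE)
  }
  FALSE
}

#' Full QC report for one image/mask pair
#'
#' @inheritParams checkSingleChamber
#' @param refGradient reference boundary gradient for flag d.
#' @return a one-row data.frame with flags a-e, `excluded` (their OR) and
#'   diagnostic measurements.
#' @export
qcFlags <- function(image, mask, refGradient = 0.15) {
  grad <- .boundaryGradient(image, mask)
  support <- sectorSupport(image)
  outside <- sum((mask > 0) & !support) / max(1, sum(mask > 0))
  darkWall <- if (sum(mask == 2L) > 0)
    sum((image < 0.05) & support & (mask == 2L)) / sum(mask == 2L) else 0
  fa <- checkSingleChamber(image, mask)
  fb <- checkTruncatedBottom(mask)
  fc_ <- checkBeyondSector(image, mask)
  fd <- checkBlurredBoundary(image, mask, refGradient = refGradient)
  fe <- checkBlackRegion(image, mask)
  data.frame(flag_a = fa, flag_b = fb, flag_c = fc_, flag_d = fd, flag_e = fe,
             excluded = fa | fb | fc_ | fd | fe,
             boundary_gradient = grad, outside_sector_frac = outside,
             dark_wall_frac = darkWall)
}

#' Apply the clean-subset exclusion criteria to a dataset
#'
#' Computes all five flags per image (the blurred-boundary reference is the
#' dataset median boundary gradient) and returns the clean subset (no flags)
#' together with the per-image report. The input dataset is untouched and
#' the operation is idempotent.
#'
#' @param dataset a list of `list(image =, mask =, id =)` entries (`id`
#'   optional).
#' @param blurFactor fraction of the median gradient below which flag d
#'   raises.
#' @return list with `clean` (subset of `dataset`) and `report`
#'   (data.frame, one row per image).
#' @export
applyExclusions <- function(dataset, blurFactor = 0.5) {
  if (length(dataset) == 0L) stop("empty dataset")
  grads <- vapply(dataset, function(d) .boundaryGradient(d$image, d$mask),
                  numeric(1))
  med <- stats::median(grads)
  rows <- lapply(seq_along(dataset), function(i) {
    d <- dataset[[i]]
    r <- qcFlags(d$image, d$mask, refGradient = med / blurFactor * 0.5)
    ## refGradient chosen so flag d compares grad < blurFactor * median
    r$flag_d <- grads[i] < blurFactor * med
    r$excluded <- with(r, flag_a | flag_b | flag_c | flag_d | flag_e)
    cbind(id = if (!is.null(d$id)) d$id else sprintf("img_%03d", i), r)
  })
  report <- do.call(rbind, rows)
  list(clean = dataset[!report$excluded], report = report)
}
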