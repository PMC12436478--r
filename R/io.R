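## Text-friendly I/O: numbered 8-bit PNG frames (or one multi-page TIFF),
## label masks as 8-bit PNGs storing the raw label values, JSON sidecars for
## phantom truth and sequence metadata, and the flat cohort / strain CSV
## schemas.

#' Write an echo sequence to disk
#'
#' Frames as `frame_000.png ...` 8-bit grayscale (or one multi-page TIFF
#' when `format = "tiff"`), plus a `meta.json` sidecar with the R-peak
#' index, pixel spacing and id.
#'
#' @param sequence an [EchoSequence-class].
#' @param dir output directory (created if needed).
#' @param format `"png"` or `"tiff"`.
#' @return `dir`, invisibly.
#' @export
writeEchoSequence <- function(sequence, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frs <- sequence@frames
  if (format == "png") {
    for (i in seq_along(frs))
      png::writePNG(frs[[i]], file.path(dir, sprintf("frame_%03d.png", i - 1L)))
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required for format = \"tiff\"")
    tiff::writeTIFF(frs, file.path(dir, "frames.tiff"), bits.per.sample = 8L)
  }
  meta <- list(id = sequence@id,
               r_peak_index = if (is.na(sequence@rPeakIndex)) NULL
                              else sequence@rPeakIndex,
               pixel_spacing = if (is.na(sequence@pixelSpacing)) NULL
                               else sequence@pixelSpacing,
               n_frames = length(frs))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(dir)
}

#' Read an echo sequence written by [writeEchoSequence()]
#'
#' @param dir directory holding `frame_###.png` (or `frames.tiff`) and
#'   `meta.json`.
#' @return an [EchoSequence-class].
#' @export
readEchoSequence <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  tiffPath <- file.path(dir, "frames.tiff")
  frs <- if (file.exists(tiffPath)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required to read ", tiffPath)
    lapply(tiff::readTIFF(tiffPath, all = TRUE), function(m)
      if (length(dim(m)) == 3L) m[, , 1L] else m)
  } else {
    files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                             full.names = TRUE))
    lapply(files, function(f) {
      m <- png::readPNG(f)
      if (length(dim(m)) == 3L) m[, , 1L] else m
    })
  }
  new("EchoSequence", frames = frs,
      rPeakIndex = if (is.null(meta$r_peak_index)) NA_integer_
                   else as.integer(meta$r_peak_index),
      pixelSpacing = if (is.null(meta$pixel_spacing)) NA_real_
                     else as.numeric(meta$pixel_spacing),
      id = meta$id %||na% "seq")
}

`%||na%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a label mask sequence
#'
#' Masks as `mask_###.png`, 8-bit grayscale PNGs storing the raw label
#' values 0/1/2 (so the images look black; they are label files, not
#' pictures).
#'
#' @param maskSeq a [LabelMaskSequence-class].
#' @param dir output directory.
#' @return `dir` (write) / a [LabelMaskSequence-class] (read).
#' @export
writeMaskSequence <- function(maskSeq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ms <- maskSeq@masks
  for (i in seq_along(ms))
    png::writePNG(ms[[i]] / 255,
                  file.path(dir, sprintf("mask_%03d.png", i - 1L)))
  invisible(dir)
}

#' @rdname writeMaskSequence
#' @export
readMaskSequence <- function(dir) {
  files <- sort(list.files(dir, pattern = "^mask_\\d+\\.png$",
                           full.names = TRUE))
  ms <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  })
  new("LabelMaskSequence", masks = ms)
}

#' Write / read phantom ground truth as a JSON sidecar
#'
#' @param truth a [PhantomTruth-class].
#' @param path JSON file path.
#' @export
writePhantomTruth <- function(truth, path) {
  jsonlite::write_json(
    list(scale = truth@scale, true_strain = truth@trueStrain,
         wall_thickness = truth@wallThickness, sector = truth@sector,
         base_contour = unname(as.data.frame(truth@baseContour))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePhantomTruth
#' @export
readPhantomTruth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  bc <- as.matrix(j$base_contour)
  colnames(bc) <- c("x", "y")
  new("PhantomTruth", baseContour = bc, scale = j$scale,
      trueStrain = j$true_strain, wallThickness = j$wall_thickness,
      sector = as.list(j$sector))
}

#' Write / read a cohort CSV
#'
#' One row per patient with columns: id, age, sex, bmi, bsa, chads_vasc,
#' mi, cad, thyroid, dm, htn, ahre_minutes, ahre_burden_pct, peak_strain,
#' strain_t00 ... strain_t29 (strains as fractions).
#'
#' @param cohort cohort data.frame.
#' @param path CSV path.
#' @export
writeCohortCsv <- function(cohort, path) {
  cols <- c("id", "age", "sex", "bmi", "bsa", "chads_vasc", "mi", "cad",
            "thyroid", "dm", "htn", "ahre_minutes", "ahre_burden_pct",
            "peak_strain", sprintf("strain_t%02d", 0:29))
  utils::write.csv(cohort[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortCsv
#' @export
readCohortCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  grp <- cut(df$ahre_minutes, c(-Inf, 6, 1440, Inf), right = FALSE,
             labels = .grpNames)
  df$ahre_group <- factor(as.character(grp), levels = .grpNames)
  df
}

#' Write extracted strain curves as CSV
#'
#' @param curves a named list of [StrainCurve-class] objects (names are
#'   sequence ids).
#' @param path CSV path.
#' @export
writeStrainCsv <- function(curves, path) {
  rows <- lapply(names(curves), function(id) {
    sc <- curves[[id]]
    v <- sc@values
    stopifnot(length(v) == 30L)
    cbind(data.frame(id = id, base_index = sc@baseIndex,
                     peak_strain = max(v)),
          stats::setNames(as.data.frame(t(v)), sprintf("strain_t%02d", 0:29)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
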