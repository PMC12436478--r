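## End-to-end orchestration: patient-level stratified splitting, a demo-scale
## pipeline runner (simulate -> QC -> train segmentation -> segment -> strain
## -> train classifier -> evaluate), and config round-tripping.

#' Patient-level stratified split
#'
#' Randomly splits patients into development (80%) and test (20%) sets,
#' then splits development into training (80%) and validation (20%),
#' stratified by class label at the patient level, giving overall
#' proportions of 64/16/20% (+/- 1 patient per class).
#'
#' @param patientIds character vector of unique patient ids.
#' @param labels per-patient stratification labels (e.g. AHRE group); every
#'   class needs at least 5 patients.
#' @param devFrac development-set fraction (default 0.8).
#' @param trainFrac training fraction within development (default 0.8).
#' @param seed integer seed.
#' @return list of id vectors `train`, `val`, `test` (pairwise disjoint,
#'   union = all ids).
#' @export
splitPatients <- function(patientIds, labels, devFrac = 0.8, trainFrac = 0.8,
                          seed = 1L) {
  if (anyDuplicated(patientIds)) stop("patient ids must be unique")
  tab <- table(labels)
  if (any(tab < 5L)) stop("every class needs at least 5 patients")
  old <- .Random.seed_exists()
  set.seed(seed)
  train <- character(0); val <- character(0); test <- character(0)
  for (cl in names(tab)) {
    ids <- sample(patientIds[labels == cl])
    n <- length(ids)
    nTest <- round((1 - devFrac) * n)
    nVal <- round((1 - trainFrac) * (n - nTest))
    test <- c(test, ids[seq_len(nTest)])
    val <- c(val, ids[nTest + seq_len(nVal)])
    train <- c(train, ids[(nTest + nVal + 1L):n])
  }
  .restoreSeed(old)
  list(train = train, val = val, test = test)
}

#' Demo-scale pipeline configuration
#'
#' Settings for [runPipeline()]. The defaults describe a desk-scale run
#' (small images, few epochs) that exercises every stage end to end; the
#' full-scale settings of the individual modules remain available through
#' `segConfig()` / `clfConfig()` overrides.
#'
#' @param outDir output directory for artifacts.
#' @param nPhantoms phantom sequences for segmentation training.
#' @param nTestPhantoms held-out phantoms for strain validation.
#' @param phantomSize phantom image side (pixels).
#' @param framesPerPhantom frames per phantom.
#' @param cohortN synthetic cohort size.
#' @param seg a [segConfig()] for the segmentation stage.
#' @param clf a [clfConfig()] for the classification stage.
#' @param threshold AHRE threshold evaluated.
#' @param seed global seed; per-stage seeds are derived from it.
#' @return a config list that round-trips through YAML.
#' @export
pipelineConfig <- function(outDir = tempfile("echostrain_run_"),
                           nPhantoms = 8L, nTestPhantoms = 3L,
                           phantomSize = 64L, framesPerPhantom = 10L,
                           cohortN = 300L,
                           seg = segConfig(arch = "resunetpp", inputSize = 64L,
                                           epochs = 8L, batchSize = 8L,
                                           baseWidth = 8L),
                           clf = clfConfig(threshold = "24h", epochs = 40L,
                                           width = 32L, depth = 1L),
                           threshold = "24h", seed = 1L) {
  list(outDir = outDir, nPhantoms = as.integer(nPhantoms),
       nTestPhantoms = as.integer(nTestPhantoms),
       phantomSize = as.integer(phantomSize),
       framesPerPhantom = as.integer(framesPerPhantom),
       cohortN = as.integer(cohortN), seg = seg, clf = clf,
       threshold = threshold, seed = as.integer(seed))
}

#' Write / read a pipeline config as YAML
#'
#' @param config a [pipelineConfig()] list.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("nPhantoms", "nTestPhantoms", "phantomSize", "framesPerPhantom",
              "cohortN", "seed"))
    cfg[[f]] <- as.integer(cfg[[f]])
  cfg
}

## deterministic per-stage seed derivation from the global seed
.stageSeed <- function(seed, stage) {
  (seed * 97L + stage * 1009L) %% 2147480000L
}

#' Run the end-to-end demo pipeline
#'
#' Executes simulate -> QC -> segmentation training -> inference -> strain
#' extraction -> cohort simulation -> classifier training -> evaluation, in
#' order, writing every artifact (masks, strain CSV, predictions, metrics,
#' manifest with config and seeds) into the output directory. The trained
#' segmentation model is checkpointed to `seg_model.rds`, and a rerun over
#' the same output directory resumes from it instead of retraining; any
#' stage failure aborts with a stage-named error while earlier artifacts
#' are retained.
#'
#' @param config a [pipelineConfig()].
#' @param verbose print per-stage progress.
#' @return invisibly, a list with the artifact paths and headline metrics
#'   (validation Dice, strain Bland-Altman vs the phantom oracle, holdout
#'   classifier report).
#' @export
runPipeline <- function(config = pipelineConfig(), verbose = TRUE) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  manifestPath <- file.path(config$outDir, "manifest.json")
  t0 <- proc.time()[3]

  ## stage 1: simulate phantoms
  phN <- config$nPhantoms + config$nTestPhantoms
  phantoms <- stage("simulate", {
    say("[1/6] simulating %d phantoms", phN)
    lapply(seq_len(phN), function(i)
      makePhantom(phantomParams(size = config$phantomSize,
                                nframes = config$framesPerPhantom,
                                sMax = 1 + 0.1 + 0.2 * (i %% 3) / 2),
                  seed = .stageSeed(config$seed, i), id = sprintf("ph%02d", i)))
  })
  trainPh <- phantoms[seq_len(config$nPhantoms)]
  testPh <- phantoms[(config$nPhantoms + 1L):phN]

  ## stage 2: QC on the training frames
  qcPath <- file.path(config$outDir, "qc_report.csv")
  clean <- stage("qc", {
    say("[2/6] quality control")
    pairs <- unlist(lapply(trainPh, function(ph)
      lapply(seq_len(config$framesPerPhantom), function(t)
        list(image = ph$sequence@frames[[t]], mask = ph$masks@masks[[t]],
             id = sprintf("%s_f%02d", ph$sequence@id, t)))), recursive = FALSE)
    ex <- applyExclusions(pairs)
    utils::write.csv(ex$report, qcPath, row.names = FALSE)
    ex$clean
  })

  ## stage 3: train segmentation
  segPath <- file.path(config$outDir, "seg_loss.csv")
  ckptPath <- file.path(config$outDir, "seg_model.rds")
  segModel <- stage("train-seg", {
    if (file.exists(ckptPath)) {
      say("[3/6] resuming segmenter from %s", ckptPath)
      readRDS(ckptPath)
    } else {
      say("[3/6] training %s segmenter on %d clean frames",
          config$seg$arch, length(clean))
      cfg <- config$seg
      cfg$seed <- .stageSeed(config$seed, 101L)
      m <- trainSegmenter(clean, config = cfg)
      utils::write.csv(data.frame(epoch = seq_along(m@lossLog),
                                  loss = m@lossLog), segPath, row.names = FALSE)
      saveRDS(m, ckptPath)
      m
    }
  })

  ## stage 4: segment held-out phantoms + strain extraction
  strainPath <- file.path(config$outDir, "strain.csv")
  strainRes <- stage("strain", {
    say("[4/6] segmenting %d held-out phantoms and extracting strain",
        length(testPh))
    curves <- list(); truthPeaks <- numeric(0); extrPeaks <- numeric(0)
    dices <- numeric(0)
    for (ph in testPh) {
      pred <- segmentSequence(segModel, ph$sequence)
      dices <- c(dices, mean(vapply(seq_len(nFrames(pred)), function(t)
        diceCoef(pred@masks[[t]], ph$masks@masks[[t]], 1L), numeric(1))))
      sc <- sequenceToStrain(pred, rPeakIndex = ph$sequence@rPeakIndex,
                             resample = FALSE)
      truthPeaks <- c(truthPeaks, max(ph$truth@trueStrain))
      extrPeaks <- c(extrPeaks, peakStrain(sc))
      if (nFrames(ph$masks) >= 30L)
        curves[[ph$sequence@id]] <- resampleEquidistant(sc)
    }
    if (length(curves)) writeStrainCsv(curves, strainPath)
    list(meanCavityDice = mean(dices),
         ba = if (length(truthPeaks) >= 2L)
           blandAltman(extrPeaks, truthPeaks) else NULL,
         peaks = data.frame(truth = truthPeaks, extracted = extrPeaks))
  })

  ## stage 5: cohort + classifier
  cohortPath <- file.path(config$outDir, "cohort.csv")
  clfRes <- stage("train-clf", {
    say("[5/6] simulating cohort (n = %d) and training classifier",
        config$cohortN)
    cohort <- simulateCohort(config$cohortN, seed = .stageSeed(config$seed, 201L))
    writeCohortCsv(cohort, cohortPath)
    rep <- evaluateClassifier(cohort, threshold = config$threshold,
                              protocol = "holdout", config = config$clf,
                              seed = .stageSeed(config$seed, 202L))
    rep
  })

  ## stage 6: manifest
  stage("report", {
    say("[6/6] writing manifest")
    jsonlite::write_json(list(
      config = config[setdiff(names(config), c("seg", "clf"))],
      seg = config$seg, clf = config$clf,
      metrics = list(val_cavity_dice = strainRes$meanCavityDice,
                     strain_bias = strainRes$ba$bias,
                     holdout_auc = clfRes$auc),
      elapsed_sec = unname(proc.time()[3] - t0),
      r_version = R.version.string),
      manifestPath, auto_unbox = TRUE, digits = NA, null = "null")
  })
  invisible(list(outDir = config$outDir, qcReport = qcPath,
                 strainCsv = strainPath, cohortCsv = cohortPath,
                 manifest = manifestPath, segModel = segModel,
                 dice = strainRes$meanCavityDice, blandAltman = strainRes$ba,
                 classifier = clfRes))
}
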