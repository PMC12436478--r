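## Transformer AHRE classification.
##
## Inputs are the 30-point resampled strain curve plus the ten clinical
## features (age, sex, BMI, BSA, CHA2DS2-VASc, MI, CAD, thyroid disease,
## DM, HTN). Each strain value becomes one token (linear embedding +
## sinusoidal positional encoding); the ten features are projected to one
## prepended summary token, keeping multi-head attention focused on the
## longitudinal relationships between strain timestamps. The pooled summary
## token feeds a sigmoid head trained with class-imbalance-weighted binary
## cross-entropy.

#' Classifier configuration
#'
#' @param threshold AHRE duration threshold defining the positive class:
#'   `"6min"` or `"24h"`.
#' @param depth number of transformer encoder layers.
#' @param heads attention heads (`width` must be divisible by `heads`).
#' @param width model (embedding) width.
#' @param ffMult feed-forward expansion factor.
#' @param epochs training epochs (default 400).
#' @param learningRate initial Adam learning rate, cosine-annealed to zero.
#' @param batchSize minibatch size.
#' @param dropout dropout rate during training.
#' @param posWeight `"auto"` (negatives/positives from the training labels)
#'   or a positive number.
#' @param seed integer seed.
#' @return a validated config list.
#' @export
clfConfig <- function(threshold = c("24h", "6min"), depth = 2L, heads = 4L,
                      width = 64L, ffMult = 2L, epochs = 400L,
                      learningRate = 0.001, batchSize = 32L, dropout = 0.1,
                      posWeight = "auto", seed = 1L) {
  threshold <- match.arg(threshold)
  if (width %% heads != 0L) stop("width must be divisible by heads")
  if (!identical(posWeight, "auto") && (!is.numeric(posWeight) || posWeight <= 0))
    stop("posWeight must be \"auto\" or a positive number")
  list(threshold = threshold, depth = as.integer(depth),
       heads = as.integer(heads), width = as.integer(width),
       ffMult = as.integer(ffMult), epochs = as.integer(epochs),
       learningRate = learningRate, batchSize = as.integer(batchSize),
       dropout = dropout, posWeight = posWeight, seed = as.integer(seed))
}

#' Binary AHRE label at a duration threshold
#'
#' 1 when the longest AHRE duration reaches the threshold (boundary
#' inclusive: exactly 6 min is positive at the 6-min threshold).
#'
#' @param ahreMinutes non-negative AHRE duration(s) in minutes.
#' @param threshold `"6min"`, `"24h"`, or a numeric threshold in minutes.
#' @return integer 0/1 vector.
#' @examples
#' thresholdLabel(c(5, 6, 25 * 60), "6min")   # 0 1 1
#' @export
thresholdLabel <- function(ahreMinutes, threshold = "6min") {
  if (any(ahreMinutes < 0)) stop("AHRE duration must be non-negative")
  thr <- if (is.numeric(threshold)) threshold
  else switch(match.arg(threshold, c("6min", "24h")),
              "6min" = 6, "24h" = 24 * 60)
  as.integer(ahreMinutes >= thr)
}

#' Weighted binary cross-entropy
#'
#' `-(wPos * y * log(p) + (1 - y) * log(1 - p))`, elementwise; reduces to
#' standard BCE at `wPos = 1`.
#'
#' @param p predicted probabilities, strictly inside (0, 1).
#' @param y binary labels.
#' @param wPos positive-class weight (> 0).
#' @return numeric vector of losses (same length as `p`).
#' @examples
#' weightedBce(0.5, 1, 2)  # 2 * log(2)
#' @export
weightedBce <- function(p, y, wPos = 1) {
  if (any(p <= 0 | p >= 1)) stop("probabilities must lie strictly in (0, 1)")
  if (wPos <= 0) stop("wPos must be positive")
  -(wPos * y * log(p) + (1 - y) * log(1 - p))
}

#' Positive-class weight from class imbalance
#'
#' The ratio of negatives to positives, the standard weighting that
#' rebalances a weighted BCE loss.
#'
#' @param labels binary labels with both classes present.
#' @return negatives/positives.
#' @examples
#' autoPosWeight(rep(c(0, 1), c(90, 10)))  # 9
#' @export
autoPosWeight <- function(labels) {
  y <- as.integer(as.logical(labels))
  nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
  if (nPos == 0L || nNeg == 0L) stop("both classes must be present")
  nNeg / nPos
}

.posEncoding <- function(d, Tn) {
  pe <- matrix(0, d, Tn)
  pos <- seq_len(Tn) - 1L
  for (i in seq_len(d %/% 2L)) {
    f <- 1 / 10000^(2 * (i - 1) / d)
    pe[2L * i - 1L, ] <- sin(pos * f)
    pe[2L * i, ] <- cos(pos * f)
  }
  pe
}

.xavier <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, 0, sqrt(2 / (nin + nout))), nout)
}

## Forward graph. strain: (30 x B) matrix, feats: (10 x B) standardized.
.clfForward <- function(ctx, strain, feats) {
  cfg <- ctx$cfg
  tp <- ctx$tp
  d <- cfg$width
  Tn <- nrow(strain)
  B <- ncol(strain)
  We <- .pnode(ctx, "emb.W", function() .xavier(d, 1L))
  be <- .pnode(ctx, "emb.b", function() numeric(d))
  sv <- tapeConst(tp, matrix(as.vector(strain), 1L))       # 1 x T*B
  xs <- opDense(tp, We, sv, be)
  pe <- .posEncoding(d, Tn)
  xs <- opAdd(tp, xs, tapeConst(tp, pe[, rep(seq_len(Tn), B), drop = FALSE]))
  Wf <- .pnode(ctx, "feat.W", function() .xavier(d, nrow(feats)))
  bf <- .pnode(ctx, "feat.b", function() numeric(d))
  tok <- opDense(tp, Wf, tapeConst(tp, feats), bf)
  x <- opPrependToken(tp, tok, xs, Tn, B)
  T1 <- Tn + 1L
  for (l in seq_len(cfg$depth)) {
    nm <- function(s) sprintf("l%d.%s", l, s)
    g1 <- .pnode(ctx, nm("ln1.g"), function() rep(1, d))
    b1 <- .pnode(ctx, nm("ln1.b"), function() numeric(d))
    h <- opLayerNorm(tp, x, g1, b1)
    Wq <- .pnode(ctx, nm("Wq"), function() .xavier(d, d))
    Wk <- .pnode(ctx, nm("Wk"), function() .xavier(d, d))
    Wv <- .pnode(ctx, nm("Wv"), function() .xavier(d, d))
    Wo <- .pnode(ctx, nm("Wo"), function() .xavier(d, d))
    bo <- .pnode(ctx, nm("bo"), function() numeric(d))
    att <- opAttention(tp, opDense(tp, Wq, h), opDense(tp, Wk, h),
                       opDense(tp, Wv, h), T1, B, cfg$heads)
    att <- opDense(tp, Wo, att, bo)
    att <- opDropout(tp, att, cfg$dropout, ctx$training)
    x <- opAdd(tp, x, att)
    g2 <- .pnode(ctx, nm("ln2.g"), function() rep(1, d))
    b2 <- .pnode(ctx, nm("ln2.b"), function() numeric(d))
    h2 <- opLayerNorm(tp, x, g2, b2)
    f <- cfg$ffMult * d
    W1 <- .pnode(ctx, nm("ff.W1"), function() .xavier(f, d))
    bf1 <- .pnode(ctx, nm("ff.b1"), function() numeric(f))
    W2 <- .pnode(ctx, nm("ff.W2"), function() .xavier(d, f))
    bf2 <- .pnode(ctx, nm("ff.b2"), function() numeric(d))
    ff <- opDense(tp, W2, opRelu(tp, opDense(tp, W1, h2, bf1)), bf2)
    ff <- opDropout(tp, ff, cfg$dropout, ctx$training)
    x <- opAdd(tp, x, ff)
  }
  gf <- .pnode(ctx, "lnf.g", function() rep(1, d))
  bfn <- .pnode(ctx, "lnf.b", function() numeric(d))
  x <- opLayerNorm(tp, x, gf, bfn)
  pooled <- opSelectToken(tp, x, T1, B, 1L)
  Wh <- .pnode(ctx, "head.W", function() .xavier(1L, d))
  bh <- .pnode(ctx, "head.b", function() numeric(1L))
  opDense(tp, Wh, pooled, bh)                              # logits, 1 x B
}

.standardizeFeatures <- function(feats, center = NULL, scale = NULL,
                                 keepBinary = TRUE) {
  feats <- as.matrix(feats)
  if (is.null(center)) {
    isBin <- keepBinary & apply(feats, 2, function(v) all(v %in% c(0, 1)))
    center <- ifelse(isBin, 0, colMeans(feats))
    scale <- ifelse(isBin, 1, apply(feats, 2, stats::sd))
    scale[!is.finite(scale) | scale < 1e-8] <- 1
  }
  list(x = sweep(sweep(feats, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

#' Train the transformer AHRE classifier
#'
#' @param strain n x 30 matrix of resampled fractional strain curves.
#' @param features n x 10 matrix/data.frame of clinical features (numerics
#'   on any scale -- they are standardized with training-set statistics that
#'   are persisted in the model -- binaries as 0/1).
#' @param labels binary outcome labels (>= 2 patients per class).
#' @param config a [clfConfig()].
#' @param verbose print per-epoch loss.
#' @return an [AhreClassifier-class].
#' @export
trainClassifier <- function(strain, features, labels, config = clfConfig(),
                            verbose = FALSE) {
  strain <- as.matrix(strain)
  features <- data.matrix(features)
  y <- as.integer(as.logical(labels))
  if (ncol(strain) != 30L) stop("strain input must have exactly 30 columns")
  if (ncol(features) != 10L) stop("feature input must have exactly 10 columns")
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    stop("need at least 2 patients per class")
  if (any(!is.finite(strain)) || any(!is.finite(features)))
    stop("inputs must have no missing entries")
  wPos <- if (identical(config$posWeight, "auto")) autoPosWeight(y)
          else config$posWeight
  std <- .standardizeFeatures(features)
  stdS <- .standardizeFeatures(strain, keepBinary = FALSE)
  n <- nrow(strain)
  old <- .Random.seed_exists()
  set.seed(config$seed)
  params <- new.env(parent = emptyenv())
  ctx <- .ctxNew(tapeNew(), params, initMode = TRUE, cfg = config)
  .clfForward(ctx, t(stdS$x[1:2, , drop = FALSE]), t(std$x[1:2, , drop = FALSE]))
  plist <- .paramsAsList(params)
  opt <- adamInit(plist)
  nb <- ceiling(n / config$batchSize)
  lossLog <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    lr <- cosineAnnealLr(epoch - 1L, config$epochs, config$learningRate)
    ord <- sample(n)
    eloss <- 0
    for (b in seq_len(nb)) {
      sel <- ord[((b - 1L) * config$batchSize + 1L):min(b * config$batchSize, n)]
      tp <- tapeNew()
      pn <- lapply(plist, function(p) tapeParam(tp, p))
      ctx <- .ctxNew(tp, .listAsEnv(plist), pnodes = pn, cfg = config,
                     training = TRUE)
      logits <- .clfForward(ctx, t(stdS$x[sel, , drop = FALSE]),
                            t(std$x[sel, , drop = FALSE]))
      loss <- opWeightedBceLoss(tp, logits, y[sel], wPos)
      tapeBackward(tp, loss)
      st <- adamStep(plist, lapply(pn, function(nd) nd$grad), opt, lr)
      plist <- st$params
      opt <- st$state
      eloss <- eloss + loss$val
    }
    lossLog[epoch] <- eloss / nb
    if (verbose) message(sprintf("epoch %d/%d  loss %.4f", epoch,
                                 config$epochs, lossLog[epoch]))
  }
  .restoreSeed(old)
  new("AhreClassifier", params = plist, config = config,
      featCenter = as.numeric(std$center), featScale = as.numeric(std$scale),
      strainCenter = as.numeric(stdS$center),
      strainScale = as.numeric(stdS$scale), lossLog = lossLog)
}

#' Predicted AHRE probability
#'
#' Deterministic inference-mode forward pass (dropout disabled); output is a
#' probability strictly inside (0, 1) for each patient.
#'
#' @param model an [AhreClassifier-class].
#' @param strain n x 30 strain matrix.
#' @param features n x 10 feature matrix.
#' @return numeric vector of probabilities.
#' @export
predictProba <- function(model, strain, features) {
  strain <- as.matrix(strain)
  features <- data.matrix(features)
  if (ncol(strain) != 30L) stop("strain input must have exactly 30 columns")
  if (ncol(features) != 10L) stop("feature input must have exactly 10 columns")
  std <- .standardizeFeatures(features, model@featCenter, model@featScale)
  stdS <- .standardizeFeatures(strain, model@strainCenter, model@strainScale)
  tp <- tapeNew()
  pn <- lapply(model@params, function(p) tapeConst(tp, p))
  ctx <- .ctxNew(tp, .listAsEnv(model@params), pnodes = pn,
                 cfg = model@config, training = FALSE)
  logits <- .clfForward(ctx, t(stdS$x), t(std$x))
  p <- 1 / (1 + exp(-as.vector(logits$val)))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Classifier inputs from a cohort table
#'
#' Extracts the 30-point strain matrix, the 10-feature matrix (age, sex as
#' male = 1, BMI, BSA, CHA2DS2-VASc, MI, CAD, thyroid, DM, HTN) and the
#' binary label at the requested AHRE threshold.
#'
#' @param cohort a data.frame from [simulateCohort()] (or the same schema).
#' @param threshold `"6min"` or `"24h"`.
#' @return list with `strain`, `features`, `labels`.
#' @export
cohortToInputs <- function(cohort, threshold = "24h") {
  sc <- as.matrix(cohort[, sprintf("strain_t%02d", 0:29)])
  feats <- cbind(age = cohort$age,
                 sex = as.integer(cohort$sex == "male"),
                 bmi = cohort$bmi, bsa = cohort$bsa,
                 chads_vasc = cohort$chads_vasc, mi = cohort$mi,
                 cad = cohort$cad, thyroid = cohort$thyroid,
                 dm = cohort$dm, htn = cohort$htn)
  list(strain = sc, features = feats,
       labels = thresholdLabel(cohort$ahre_minutes, threshold))
}

#' Evaluate the AHRE classifier on a cohort
#'
#' Hold-out protocol: one stratified 80/20 split, train on 80%, report AUC
#' and the Youden operating point on the held-out 20%. cv5 protocol:
#' stratified fivefold cross-validation with per-fold reports plus
#' mean +/- sd of each metric.
#'
#' @param cohort cohort data.frame.
#' @param threshold `"6min"` or `"24h"`.
#' @param protocol `"holdout"` or `"cv5"`.
#' @param config a [clfConfig()].
#' @param seed seed for the split/folds.
#' @return for `"holdout"`, a [rocReport()] list; for `"cv5"`, a list with
#'   `perFold` (data.frame), `mean` and `sd` of auc/accuracy/sensitivity/
#'   specificity.
#' @export
evaluateClassifier <- function(cohort, threshold = "24h",
                               protocol = c("holdout", "cv5"),
                               config = clfConfig(threshold = threshold),
                               seed = 1L) {
  protocol <- match.arg(protocol)
  inp <- cohortToInputs(cohort, threshold)
  folds <- stratifiedKfold(inp$labels, k = 5L, seed = seed)
  evalFold <- function(f, foldSeed) {
    cfg <- config
    cfg$seed <- foldSeed
    fit <- trainClassifier(inp$strain[f$train, , drop = FALSE],
                           inp$features[f$train, , drop = FALSE],
                           inp$labels[f$train], cfg)
    p <- predictProba(fit, inp$strain[f$test, , drop = FALSE],
                      inp$features[f$test, , drop = FALSE])
    rocReport(p, inp$labels[f$test])
  }
  if (protocol == "holdout") return(evalFold(folds[[1L]], config$seed))
  reps <- lapply(seq_along(folds), function(i)
    evalFold(folds[[i]], config$seed + i))
  perFold <- do.call(rbind, lapply(seq_along(reps), function(i)
    data.frame(fold = i, auc = reps[[i]]$auc, accuracy = reps[[i]]$accuracy,
               sensitivity = reps[[i]]$sensitivity,
               specificity = reps[[i]]$specificity)))
  metr <- perFold[, c("auc", "accuracy", "sensitivity", "specificity")]
  list(protocol = "cv5", perFold = perFold,
       mean = colMeans(metr), sd = apply(metr, 2, stats::sd))
}
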