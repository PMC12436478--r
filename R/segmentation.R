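## Multi-class LA segmentation.
##
## Four encoder-decoder families segment background / cavity / wall with a
## 3-class softmax head, trained with soft Dice + cross-entropy under random
## rotation and random-crop augmentation, Adam, and a cosine-annealed
## learning rate. Depth and width default small so that training at desk
## scale on one CPU is practical; all four architectures share one input and
## output contract and one training loop.

#' Segmentation configuration
#'
#' @param arch one of `"resunetpp"` (residual squeeze-excitation blocks,
#'   atrous-pyramid bridge, attention-gated decoder), `"unet_gn"` (plain
#'   U-Net with group normalization), `"unet16"` (U-Net with a deeper
#'   VGG-style stacked-convolution encoder) or `"deeplab_like"` (atrous
#'   spatial pyramid over a strided encoder, no skip decoder).
#' @param inputSize square model input size in pixels (>= 32; default 224).
#' @param epochs training epochs (default 400).
#' @param learningRate initial learning rate for Adam, annealed to zero on a
#'   cosine schedule (default 0.001).
#' @param cropScaleRange range of random-crop areas relative to the image
#'   (default `c(0.6, 1)`; must lie within (0, 1]).
#' @param rotationRange random rotation range in degrees (+/-).
#' @param batchSize minibatch size.
#' @param baseWidth channel count of the first stage; deeper stages double
#'   it.
#' @param groups channel groups for group normalization.
#' @param augment apply augmentation during training.
#' @param seed integer seed controlling initialization and batching.
#' @return a validated config list (3 classes: background/cavity/wall).
#' @export
segConfig <- function(arch = c("resunetpp", "unet_gn", "unet16", "deeplab_like"),
                      inputSize = 224L, epochs = 400L, learningRate = 0.001,
                      cropScaleRange = c(0.6, 1), rotationRange = 15,
                      batchSize = 8L, baseWidth = 8L, groups = 4L,
                      augment = TRUE, seed = 1L) {
  arch <- match.arg(arch)
  if (inputSize < 32L) stop("inputSize must be at least 32")
  if (any(cropScaleRange <= 0) || any(cropScaleRange > 1) ||
      cropScaleRange[1] > cropScaleRange[2])
    stop("cropScaleRange must lie within (0, 1]")
  list(arch = arch, inputSize = as.integer(inputSize),
       epochs = as.integer(epochs), learningRate = learningRate,
       cropScaleRange = cropScaleRange, rotationRange = rotationRange,
       batchSize = as.integer(batchSize), baseWidth = as.integer(baseWidth),
       groups = as.integer(groups), augment = augment,
       seed = as.integer(seed), classes = 3L)
}

## ---- parameter registry / forward-graph helpers ---------------------------

.ctxNew <- function(tp, params, pnodes = NULL, initMode = FALSE,
                    training = FALSE, cfg = NULL) {
  ctx <- new.env(parent = emptyenv())
  ctx$tp <- tp; ctx$params <- params; ctx$pnodes <- pnodes
  ctx$initMode <- initMode; ctx$training <- training; ctx$cfg <- cfg
  ctx
}

.pnode <- function(ctx, name, make) {
  if (is.null(ctx$params[[name]])) {
    if (!ctx$initMode) stop("unknown parameter ", name)
    ctx$params[[name]] <- make()
  }
  if (ctx$initMode) tapeConst(ctx$tp, ctx$params[[name]])
  else ctx$pnodes[[name]]
}

.cv <- function(ctx, name, x, H, W, N, cout, k = 3L, stride = 1L, dil = 1L) {
  cin <- nrow(x$val)
  Wn <- .pnode(ctx, paste0(name, ".W"), function()
    matrix(stats::rnorm(cout * cin * k * k, 0, sqrt(2 / (cin * k * k))), cout))
  bn <- .pnode(ctx, paste0(name, ".b"), function() numeric(cout))
  opConv(ctx$tp, x, Wn, bn, H, W, N, k, stride, dil)
}

.gnorm <- function(ctx, name, x, HW, N) {
  C <- nrow(x$val)
  g <- .pnode(ctx, paste0(name, ".g"), function() rep(1, C))
  b <- .pnode(ctx, paste0(name, ".be"), function() numeric(C))
  ng <- if (C %% ctx$cfg$groups == 0L) ctx$cfg$groups else 1L
  opGroupNorm(ctx$tp, x, g, b, ng, HW, N)
}

.cgr <- function(ctx, name, x, H, W, N, cout, k = 3L, stride = 1L, dil = 1L) {
  y <- .cv(ctx, name, x, H, W, N, cout, k, stride, dil)
  Ho <- if (stride == 2L) H %/% 2L else H
  Wo <- if (stride == 2L) W %/% 2L else W
  opRelu(ctx$tp, .gnorm(ctx, name, y, Ho * Wo, N))
}

.seBlock <- function(ctx, name, x, HW, N) {
  C <- nrow(x$val)
  mid <- max(2L, C %/% 4L)
  p <- opGlobalAvgPool(ctx$tp, x, HW, N)
  W1 <- .pnode(ctx, paste0(name, ".W1"), function()
    matrix(stats::rnorm(mid * C, 0, sqrt(2 / C)), mid))
  b1 <- .pnode(ctx, paste0(name, ".b1"), function() numeric(mid))
  W2 <- .pnode(ctx, paste0(name, ".W2"), function()
    matrix(stats::rnorm(C * mid, 0, sqrt(2 / mid)), C))
  b2 <- .pnode(ctx, paste0(name, ".b2"), function() numeric(C))
  s <- opSigmoid(ctx$tp, opDense(ctx$tp, W2,
         opRelu(ctx$tp, opDense(ctx$tp, W1, p, b1)), b2))
  opChannelScale(ctx$tp, x, s, HW, N)
}

.resSE <- function(ctx, name, x, H, W, N, cout, stride = 1L) {
  cin <- nrow(x$val)
  Ho <- if (stride == 2L) H %/% 2L else H
  Wo <- if (stride == 2L) W %/% 2L else W
  y <- .cgr(ctx, paste0(name, ".c1"), x, H, W, N, cout, stride = stride)
  y <- .gnorm(ctx, paste0(name, ".c2"),
              .cv(ctx, paste0(name, ".c2"), y, Ho, Wo, N, cout), Ho * Wo, N)
  sc <- if (cin != cout || stride != 1L)
    .cv(ctx, paste0(name, ".sc"), x, H, W, N, cout, k = 1L, stride = stride)
  else x
  z <- opRelu(ctx$tp, opAdd(ctx$tp, y, sc))
  .seBlock(ctx, paste0(name, ".se"), z, Ho * Wo, N)
}

.attnGate <- function(ctx, name, up, skip, HW, N) {
  a <- opAdd(ctx$tp,
             .cv(ctx, paste0(name, ".u"), up, 1L, HW, N, 4L, k = 1L),
             .cv(ctx, paste0(name, ".s"), skip, 1L, HW, N, 4L, k = 1L))
  ## 1x1 convs are spatial-size agnostic: treat the map as 1 x HW
  g <- opSigmoid(ctx$tp,
                 .cv(ctx, paste0(name, ".psi"), opRelu(ctx$tp, a),
                     1L, HW, N, 1L, k = 1L))
  opSpatialScale(ctx$tp, skip, g)
}

## ---- the four architectures -----------------------------------------------

.segForward <- function(ctx, x, H, W, N) {
  c0 <- ctx$cfg$baseWidth
  tp <- ctx$tp
  switch(ctx$cfg$arch,
    resunetpp = {
      s <- .cgr(ctx, "stem", x, H, W, N, c0)
      e1 <- .resSE(ctx, "e1", s, H, W, N, c0)
      e2 <- .resSE(ctx, "e2", e1, H, W, N, 2L * c0, stride = 2L)
      H2 <- H %/% 2L; W2 <- W %/% 2L
      e3 <- .resSE(ctx, "e3", e2, H2, W2, N, 4L * c0, stride = 2L)
      H4 <- H %/% 4L; W4 <- W %/% 4L
      br <- .asppBlock(ctx, "aspp", e3, H4, W4, N, 4L * c0)
      u2 <- opUpsample2(tp, br, H4, W4, N)
      g2 <- .attnGate(ctx, "ag2", u2, e2, H2 * W2, N)
      d2 <- .cgr(ctx, "d2", opConcatRows(tp, u2, g2), H2, W2, N, 2L * c0)
      u1 <- opUpsample2(tp, d2, H2, W2, N)
      g1 <- .attnGate(ctx, "ag1", u1, e1, H * W, N)
      d1 <- .cgr(ctx, "d1", opConcatRows(tp, u1, g1), H, W, N, c0)
      .cv(ctx, "head", d1, H, W, N, ctx$cfg$classes, k = 1L)
    },
    unet_gn = {
      e1 <- .cgr(ctx, "e1b", .cgr(ctx, "e1a", x, H, W, N, c0), H, W, N, c0)
      H2 <- H %/% 2L; W2 <- W %/% 2L
      e2 <- .cgr(ctx, "e2b",
                 .cgr(ctx, "e2a", e1, H, W, N, 2L * c0, stride = 2L),
                 H2, W2, N, 2L * c0)
      H4 <- H %/% 4L; W4 <- W %/% 4L
      e3 <- .cgr(ctx, "e3b",
                 .cgr(ctx, "e3a", e2, H2, W2, N, 4L * c0, stride = 2L),
                 H4, W4, N, 4L * c0)
      d2 <- .cgr(ctx, "d2",
                 opConcatRows(tp, opUpsample2(tp, e3, H4, W4, N), e2),
                 H2, W2, N, 2L * c0)
      d1 <- .cgr(ctx, "d1",
                 opConcatRows(tp, opUpsample2(tp, d2, H2, W2, N), e1),
                 H, W, N, c0)
      .cv(ctx, "head", d1, H, W, N, ctx$cfg$classes, k = 1L)
    },
    unet16 = {
      ## VGG-style encoder: stacked 3x3 convolutions per stage
      e1 <- .cgr(ctx, "e1b", .cgr(ctx, "e1a", x, H, W, N, c0), H, W, N, c0)
      H2 <- H %/% 2L; W2 <- W %/% 2L
      t2 <- .cgr(ctx, "e2a", e1, H, W, N, 2L * c0, stride = 2L)
      e2 <- .cgr(ctx, "e2c", .cgr(ctx, "e2b", t2, H2, W2, N, 2L * c0),
                 H2, W2, N, 2L * c0)
      H4 <- H %/% 4L; W4 <- W %/% 4L
      t3 <- .cgr(ctx, "e3a", e2, H2, W2, N, 4L * c0, stride = 2L)
      e3 <- .cgr(ctx, "e3c", .cgr(ctx, "e3b", t3, H4, W4, N, 4L * c0),
                 H4, W4, N, 4L * c0)
      d2 <- .cgr(ctx, "d2",
                 opConcatRows(tp, opUpsample2(tp, e3, H4, W4, N), e2),
                 H2, W2, N, 2L * c0)
      d1 <- .cgr(ctx, "d1",
                 opConcatRows(tp, opUpsample2(tp, d2, H2, W2, N), e1),
                 H, W, N, c0)
      .cv(ctx, "head", d1, H, W, N, ctx$cfg$classes, k = 1L)
    },
    deeplab_like = {
      s <- .cgr(ctx, "stem", x, H, W, N, c0)
      H2 <- H %/% 2L; W2 <- W %/% 2L
      e2 <- .cgr(ctx, "e2", s, H, W, N, 2L * c0, stride = 2L)
      H4 <- H %/% 4L; W4 <- W %/% 4L
      e3 <- .cgr(ctx, "e3", e2, H2, W2, N, 4L * c0, stride = 2L)
      br <- .asppBlock(ctx, "aspp", e3, H4, W4, N, 4L * c0)
      logits4 <- .cv(ctx, "head", br, H4, W4, N, ctx$cfg$classes, k = 1L)
      opUpsample2(tp, opUpsample2(tp, logits4, H4, W4, N), H2, W2, N)
    })
}

.asppBlock <- function(ctx, name, x, H, W, N, cout) {
  a1 <- .cv(ctx, paste0(name, ".d1"), x, H, W, N, cout, k = 3L, dil = 1L)
  a2 <- .cv(ctx, paste0(name, ".d2"), x, H, W, N, cout, k = 3L, dil = 2L)
  a4 <- .cv(ctx, paste0(name, ".d4"), x, H, W, N, cout, k = 3L, dil = 4L)
  y <- opAdd(ctx$tp, opAdd(ctx$tp, a1, a2), a4)
  opRelu(ctx$tp, .gnorm(ctx, paste0(name, ".n"), y, H * W, N))
}

## ---- loss, augmentation, training, inference ------------------------------

#' Soft Dice + cross-entropy segmentation loss
#'
#' `mean_c [1 - (2 sum(p t) + eps)/(sum p + sum t + eps)]` over classes plus
#' the mean per-pixel cross-entropy. Non-negative, and (up to epsilon terms)
#' zero exactly when the prediction is the one-hot target.
#'
#' @param prob per-pixel class probabilities: an H x W x C array or a C x M
#'   matrix; probabilities must sum to 1 per pixel.
#' @param target label matrix/vector with values 0 .. C-1.
#' @param eps smoothing constant of the Dice term.
#' @return a single numeric loss value.
#' @examples
#' p <- array(0, c(2, 2, 3)); p[, , 1] <- 1
#' softDiceCeLoss(p, matrix(0L, 2, 2)) < 1e-5
#' @export
softDiceCeLoss <- function(prob, target, eps = 1e-6) {
  if (is.array(prob) && length(dim(prob)) == 3L) {
    C <- dim(prob)[3]
    prob <- t(apply(prob, 3, as.vector))
    dim(prob) <- c(C, length(prob) / C)
  }
  M <- ncol(prob); C <- nrow(prob)
  tgt <- as.integer(as.vector(target)) + 1L
  if (length(tgt) != M) stop("probability field and target shapes differ")
  if (any(tgt < 1L | tgt > C)) stop("target labels out of range")
  if (max(abs(colSums(prob) - 1)) > 1e-6)
    stop("probabilities must sum to 1 per pixel")
  Tm <- matrix(0, C, M)
  Tm[cbind(tgt, seq_len(M))] <- 1
  dice <- mean(1 - (2 * rowSums(prob * Tm) + eps) /
                 (rowSums(prob) + rowSums(Tm) + eps))
  ce <- -mean(log(pmax(prob[cbind(tgt, seq_len(M))], 1e-12)))
  dice + ce
}

#' Paired geometric augmentation of an image and its mask
#'
#' Applies one random rotation and one random crop (crop area a uniform
#' fraction of the image within `cropScaleRange`) identically to image and
#' mask, then resizes both to the configured input size -- bilinear for the
#' image, nearest-neighbour for the mask so labels are preserved. Crops that
#' would lose the entire mask are re-drawn.
#'
#' @param image grayscale matrix.
#' @param mask aligned label matrix.
#' @param config a [segConfig()].
#' @param seed optional seed.
#' @return list with `image` and `mask`, both `inputSize` x `inputSize`;
#'   the applied rotation angle and crop-area scale are attached as
#'   attributes `"angle"` and `"cropScale"`.
#' @export
augmentPair <- function(image, mask, config = segConfig(), seed = NULL) {
  if (!is.null(seed)) { old <- .Random.seed_exists(); set.seed(seed) }
  H <- nrow(image); W <- ncol(image)
  ang <- stats::runif(1, -config$rotationRange, config$rotationRange)
  if (abs(ang) > 1e-9) {
    image <- as.matrix(EBImage::rotate(image, ang, filter = "bilinear",
                                       output.dim = c(H, W), bg.col = 0))
    mask <- as.matrix(EBImage::rotate(mask, ang, filter = "none",
                                      output.dim = c(H, W), bg.col = 0))
    mask <- matrix(as.integer(round(mask)), H, W)
  }
  hadMask <- sum(mask > 0) > 0
  for (try in 1:5) {
    sc <- stats::runif(1, config$cropScaleRange[1], config$cropScaleRange[2])
    side <- max(8L, round(sqrt(sc) * min(H, W)))
    r0 <- sample.int(H - side + 1L, 1L)
    c0 <- sample.int(W - side + 1L, 1L)
    mi <- mask[r0:(r0 + side - 1L), c0:(c0 + side - 1L)]
    if (!hadMask || sum(mi > 0) > 0 || try == 5L) break
  }
  ii <- image[r0:(r0 + side - 1L), c0:(c0 + side - 1L)]
  sz <- config$inputSize
  ii <- as.matrix(EBImage::resize(ii, w = sz, h = sz, filter = "bilinear"))
  mi <- as.matrix(EBImage::resize(mi, w = sz, h = sz, filter = "none"))
  if (!is.null(seed)) .restoreSeed(old)
  out <- list(image = pmin(pmax(ii, 0), 1),
              mask = matrix(as.integer(round(mi)), sz, sz))
  attr(out, "angle") <- ang
  attr(out, "cropScale") <- sc
  out
}

.batchTensors <- function(pairs, sz) {
  N <- length(pairs)
  x <- matrix(0, 1L, sz * sz * N)
  tgt <- integer(sz * sz * N)
  for (i in seq_len(N)) {
    cols <- ((i - 1L) * sz * sz + 1L):(i * sz * sz)
    x[1L, cols] <- as.vector(pairs[[i]]$image)
    tgt[cols] <- as.integer(pairs[[i]]$mask) + 1L
  }
  list(x = x, target = tgt)
}

.resizePair <- function(image, mask, sz) {
  if (nrow(image) != sz || ncol(image) != sz) {
    image <- as.matrix(EBImage::resize(image, w = sz, h = sz, filter = "bilinear"))
    mask <- matrix(as.integer(round(as.matrix(
      EBImage::resize(mask, w = sz, h = sz, filter = "none")))), sz, sz)
  }
  list(image = pmin(pmax(image, 0), 1), mask = mask)
}

#' Train a cavity/wall segmentation model
#'
#' Trains the configured encoder-decoder on (image, mask) pairs with soft
#' Dice + cross-entropy, Adam, and cosine-annealed learning rate. Runs are
#' reproducible for a fixed config seed.
#'
#' @param trainSet non-empty list of `list(image =, mask =)` pairs (masks
#'   labelled 0/1/2).
#' @param valSet optional validation pairs; per-epoch validation loss is not
#'   computed (validation is the caller's concern via [segmentSequence()]
#'   and [diceCoef()]), but the argument documents the intended split.
#' @param config a [segConfig()].
#' @param verbose print per-epoch losses.
#' @return a [SegModel-class] with the per-epoch training-loss log.
#' @export
trainSegmenter <- function(trainSet, valSet = NULL, config = segConfig(),
                           verbose = FALSE) {
  if (length(trainSet) == 0L) stop("empty training set")
  old <- .Random.seed_exists()
  set.seed(config$seed)
  sz <- config$inputSize
  ## instantiate parameters with a dummy forward pass
  params <- new.env(parent = emptyenv())
  ctx <- .ctxNew(tapeNew(), params, initMode = TRUE, cfg = config)
  dummy <- tapeConst(ctx$tp, matrix(0, 1L, 32L * 32L))
  .segForward(ctx, dummy, 32L, 32L, 1L)
  plist <- .paramsAsList(params)
  opt <- adamInit(plist)
  lossLog <- numeric(config$epochs)
  nb <- ceiling(length(trainSet) / config$batchSize)
  for (epoch in seq_len(config$epochs)) {
    lr <- cosineAnnealLr(epoch - 1L, config$epochs, config$learningRate)
    ord <- sample(length(trainSet))
    eloss <- 0
    for (b in seq_len(nb)) {
      sel <- ord[((b - 1L) * config$batchSize + 1L):min(b * config$batchSize,
                                                        length(trainSet))]
      pairs <- lapply(trainSet[sel], function(d) {
        if (config$augment) augmentPair(d$image, d$mask, config)
        else .resizePair(d$image, d$mask, sz)
      })
      bt <- .batchTensors(pairs, sz)
      tp <- tapeNew()
      pn <- lapply(plist, function(p) tapeParam(tp, p))
      ctx <- .ctxNew(tp, .listAsEnv(plist), pnodes = pn, cfg = config,
                     training = TRUE)
      xN <- tapeConst(tp, bt$x)
      logits <- .segForward(ctx, xN, sz, sz, length(sel))
      loss <- opDiceCeLoss(tp, logits, bt$target)
      tapeBackward(tp, loss)
      grads <- lapply(pn, function(nd) nd$grad)
      st <- adamStep(plist, grads, opt, lr)
      plist <- st$params
      opt <- st$state
      eloss <- eloss + loss$val
    }
    lossLog[epoch] <- eloss / nb
    if (verbose) message(sprintf("epoch %d/%d  lr %.5f  loss %.4f",
                                 epoch, config$epochs, lr, lossLog[epoch]))
  }
  .restoreSeed(old)
  new("SegModel", params = plist, config = config, lossLog = lossLog)
}

.paramsAsList <- function(env) {
  nm <- sort(ls(env))
  stats::setNames(lapply(nm, function(n) env[[n]]), nm)
}

.listAsEnv <- function(lst) {
  e <- new.env(parent = emptyenv())
  for (n in names(lst)) e[[n]] <- lst[[n]]
  e
}

#' Segment an echo sequence
#'
#' Per-pixel 3-class argmax segmentation of every frame: frames are resized
#' to the model input size, passed through the network, and the predicted
#' label field is resized back (nearest-neighbour) to the original frame
#' size. Deterministic for a fixed model.
#'
#' @param model a trained [SegModel-class].
#' @param sequence an [EchoSequence-class], or a list of grayscale matrices.
#' @param chunk frames per forward pass.
#' @return a [LabelMaskSequence-class].
#' @export
segmentSequence <- function(model, sequence, chunk = 4L) {
  frs <- if (is(sequence, "EchoSequence")) sequence@frames else sequence
  if (length(frs) == 0L) stop("empty sequence")
  cfg <- model@config
  sz <- cfg$inputSize
  H <- nrow(frs[[1L]]); W <- ncol(frs[[1L]])
  plist <- model@params
  out <- vector("list", length(frs))
  for (start in seq(1L, length(frs), by = chunk)) {
    sel <- start:min(start + chunk - 1L, length(frs))
    x <- matrix(0, 1L, sz * sz * length(sel))
    for (j in seq_along(sel)) {
      fr <- frs[[sel[j]]]
      if (nrow(fr) != sz || ncol(fr) != sz)
        fr <- as.matrix(EBImage::resize(fr, w = sz, h = sz, filter = "bilinear"))
      x[1L, ((j - 1L) * sz * sz + 1L):(j * sz * sz)] <- as.vector(fr)
    }
    tp <- tapeNew()
    pn <- lapply(plist, function(p) tapeConst(tp, p))
    ctx <- .ctxNew(tp, .listAsEnv(plist), pnodes = pn, cfg = cfg,
                   training = FALSE)
    logits <- .segForward(ctx, tapeConst(tp, x), sz, sz, length(sel))
    lab <- max.col(t(logits$val), ties.method = "first") - 1L
    for (j in seq_along(sel)) {
      m <- matrix(lab[((j - 1L) * sz * sz + 1L):(j * sz * sz)], sz, sz)
      if (H != sz || W != sz)
        m <- matrix(as.integer(round(as.matrix(
          EBImage::resize(m, w = W, h = H, filter = "none")))), H, W)
      out[[sel[j]]] <- m
    }
  }
  new("LabelMaskSequence", masks = out)
}
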