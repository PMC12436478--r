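## Segmentation unit tests run at miniature scale (32-64 px, handfuls of
## frames); the scaled-down training experiment with its Dice thresholds
## lives in the acceptance suite.

miniSet <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      out <- list()
      for (i in 1:2) {
        ph <- makePhantom(phantomParams(size = 64, nframes = 6,
                                        wallThickness = 2,
                                        sMax = 1.1 + 0.1 * i), seed = 30 + i)
        for (t in 1:6) out[[length(out) + 1]] <- list(
          image = frames(ph$sequence)[[t]], mask = masks(ph$masks)[[t]])
      }
      cache <<- out
    }
    cache
  }
})

test_that("augmentation preserves geometry contracts and label values", {
  d <- miniSet()[[1]]
  cfg <- segConfig(inputSize = 64L, rotationRange = 15)
  for (s in 1:5) {
    a <- augmentPair(d$image, d$mask, cfg, seed = s)
    expect_identical(dim(a$image), c(64L, 64L))
    expect_identical(dim(a$mask), c(64L, 64L))
    expect_true(all(unique(as.vector(a$mask)) %in% unique(as.vector(d$mask))))
    expect_true(all(a$image >= 0 & a$image <= 1))
  }
  ## rotation 0, crop scale 1 reproduces the (resized) input
  cfg0 <- segConfig(inputSize = 64L, rotationRange = 0,
                    cropScaleRange = c(1, 1))
  a0 <- augmentPair(d$image, d$mask, cfg0, seed = 1)
  expect_equal(a0$image, d$image, tolerance = 1e-12)
  expect_identical(a0$mask, d$mask)
})

test_that("empirical crop scales stay inside the configured (0.6, 1) range", {
  d <- miniSet()[[1]]
  cfg <- segConfig(inputSize = 32L, rotationRange = 10)
  draws <- vapply(1:1000, function(s)
    attr(augmentPair(d$image, d$mask, cfg, seed = s), "cropScale"), numeric(1))
  expect_gte(min(draws), 0.6)
  expect_lte(max(draws), 1.0)
  expect_lt(min(draws), 0.7)               # the range is actually explored
  expect_gt(max(draws), 0.9)
  angles <- vapply(1:200, function(s)
    attr(augmentPair(d$image, d$mask, cfg, seed = s), "angle"), numeric(1))
  expect_true(all(abs(angles) <= 10))
})

test_that("all four architectures share the input/output contract", {
  tr <- miniSet()[2:5]
  for (arch in c("resunetpp", "unet_gn", "unet16", "deeplab_like")) {
    cfg <- segConfig(arch = arch, inputSize = 32L, epochs = 1L,
                     batchSize = 4L, baseWidth = 4L, augment = FALSE, seed = 1)
    m <- trainSegmenter(tr, config = cfg)
    expect_s4_class(m, "SegModel")
    pred <- segmentSequence(m, list(tr[[1]]$image))
    expect_identical(dim(masks(pred)[[1]]), dim(tr[[1]]$mask))
    expect_true(all(masks(pred)[[1]] %in% 0:2))
  }
})

test_that("training reduces the loss and is seed-reproducible", {
  tr <- miniSet()
  cfg <- segConfig(arch = "resunetpp", inputSize = 48L, epochs = 4L,
                   batchSize = 6L, baseWidth = 4L, seed = 7)
  m1 <- trainSegmenter(tr, config = cfg)
  expect_lt(m1@lossLog[4], m1@lossLog[1])
  m2 <- trainSegmenter(tr, config = cfg)
  expect_equal(m1@lossLog, m2@lossLog, tolerance = 1e-12)
  expect_identical(m1@params, m2@params)
  expect_error(trainSegmenter(list(), config = cfg), "empty")
})

test_that("inference is total and deterministic", {
  tr <- miniSet()
  cfg <- segConfig(arch = "unet_gn", inputSize = 32L, epochs = 1L,
                   batchSize = 6L, baseWidth = 4L, augment = FALSE, seed = 2)
  m <- trainSegmenter(tr, config = cfg)
  blank <- matrix(0, 48, 48)
  p <- segmentSequence(m, list(blank))
  expect_identical(dim(masks(p)[[1]]), c(48L, 48L))       # no error on blank
  p1 <- segmentSequence(m, list(tr[[1]]$image))
  p2 <- segmentSequence(m, list(tr[[1]]$image))
  expect_identical(masks(p1), masks(p2))
  expect_error(segmentSequence(m, list()), "empty")
})

test_that("config validation enforces the documented ranges", {
  expect_error(segConfig(cropScaleRange = c(0, 1)), "cropScaleRange")
  expect_error(segConfig(cropScaleRange = c(0.8, 0.4)), "cropScaleRange")
  expect_error(segConfig(inputSize = 16), "inputSize")
  expect_identical(segConfig()$epochs, 400L)
  expect_identical(segConfig()$learningRate, 0.001)
  expect_identical(segConfig()$cropScaleRange, c(0.6, 1))
  expect_identical(segConfig()$inputSize, 224L)
})
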