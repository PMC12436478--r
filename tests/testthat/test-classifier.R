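## Classifier unit tests use a miniature transformer (width 16, 1 layer) on
## small cohorts; the parameter-recovery experiment with its AUC thresholds
## lives in the acceptance suite.

tinyCfg <- function(epochs = 8L, seed = 1L)
  clfConfig(threshold = "24h", depth = 1L, heads = 2L, width = 16L,
            epochs = epochs, batchSize = 32L, seed = seed)

tinyData <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohortSpec()
      spec$strainPct[2, ] <- spec$strainPct[2, ] / 2
      cache <<- cohortToInputs(simulateCohort(120, spec, seed = 77), "24h")
    }
    cache
  }
})

test_that("duration thresholds are boundary-inclusive", {
  expect_identical(thresholdLabel(5, "6min"), 0L)
  expect_identical(thresholdLabel(6, "6min"), 1L)         # exactly 6 min
  expect_identical(thresholdLabel(25 * 60, "24h"), 1L)
  expect_identical(thresholdLabel(24 * 60, "24h"), 1L)    # exactly 24 h
  expect_identical(thresholdLabel(c(0, 6, 1439, 1440), "24h"),
                   c(0L, 0L, 0L, 1L))
  expect_error(thresholdLabel(-1, "6min"), "non-negative")
})

test_that("training rejects degenerate inputs", {
  d <- tinyData()
  expect_error(trainClassifier(d$strain[1:10, ], d$features[1:10, ],
                               rep(1, 10), tinyCfg()), "per class")
  expect_error(trainClassifier(d$strain[, 1:10], d$features, d$labels,
                               tinyCfg()), "30 columns")
  expect_error(clfConfig(width = 30, heads = 4), "divisible")
})

test_that("a tiny transformer trains, predicts in (0,1), deterministically", {
  d <- tinyData()
  fit <- trainClassifier(d$strain, d$features, d$labels, tinyCfg())
  expect_s4_class(fit, "AhreClassifier")
  expect_lt(fit@lossLog[length(fit@lossLog)], fit@lossLog[1])
  p1 <- predictProba(fit, d$strain, d$features)
  p2 <- predictProba(fit, d$strain, d$features)
  expect_identical(p1, p2)                                # inference mode
  expect_true(all(p1 > 0 & p1 < 1))
  expect_error(predictProba(fit, d$strain[, 1:20], d$features), "30 columns")
  expect_error(predictProba(fit, d$strain, d$features[, 1:5]), "10 columns")
})

test_that("an untrained model still emits probabilities inside (0,1)", {
  d <- tinyData()
  cfg <- tinyCfg(epochs = 1L)
  fit <- trainClassifier(d$strain[1:40, ], d$features[1:40, ],
                         d$labels[1:40], cfg)
  p <- predictProba(fit, d$strain[41:60, ], d$features[41:60, ])
  expect_true(all(p > 0 & p < 1))
})

test_that("training runs are reproducible under a fixed seed", {
  d <- tinyData()
  f1 <- trainClassifier(d$strain, d$features, d$labels, tinyCfg(seed = 9))
  f2 <- trainClassifier(d$strain, d$features, d$labels, tinyCfg(seed = 9))
  expect_equal(f1@lossLog, f2@lossLog, tolerance = 1e-12)
  expect_identical(f1@params, f2@params)
})

test_that("cohortToInputs produces the 30 + 10 input contract", {
  co <- simulateCohort(30, seed = 2)
  inp <- cohortToInputs(co, "6min")
  expect_identical(dim(inp$strain), c(30L, 30L))
  expect_identical(dim(inp$features), c(30L, 10L))
  expect_identical(colnames(inp$features),
                   c("age", "sex", "bmi", "bsa", "chads_vasc", "mi", "cad",
                     "thyroid", "dm", "htn"))
  expect_true(all(inp$labels %in% 0:1))
  expect_identical(inp$labels, thresholdLabel(co$ahre_minutes, "6min"))
})

test_that("evaluateClassifier returns coherent holdout and cv5 reports", {
  spec <- cohortSpec()
  spec$strainPct[2, ] <- spec$strainPct[2, ] / 2
  co <- simulateCohort(150, spec, seed = 41)
  r <- evaluateClassifier(co, "6min", "holdout", tinyCfg(epochs = 6L), seed = 2)
  expect_true(all(c("auc", "sensitivity", "specificity", "accuracy") %in%
                    names(r)))
  expect_gte(r$auc, 0)
  expect_lte(r$auc, 1)
  expect_error(evaluateClassifier(co, "6min", "bootstrap"), "arg")
})
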