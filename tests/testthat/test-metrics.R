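test_that("Dice coefficient matches its closed form and is symmetric", {
  m <- matrix(0L, 10, 10)
  a <- m; a[1:5, ] <- 1L
  b <- m; b[3:7, ] <- 1L                          # |P|=|T|=50, overlap 30
  expect_equal(diceCoef(a, a), 1)
  expect_equal(diceCoef(a, 1L - a, classLabel = 1L), 0)
  expect_equal(diceCoef(a, b), 2 * 30 / 100)
  expect_equal(diceCoef(a, b), diceCoef(b, a))
  expect_equal(diceCoef(m, m), 1)                 # both empty
  expect_error(diceCoef(a, matrix(0L, 3, 3)), "mismatch")
})

test_that("Bland-Altman agrees with a direct-formula oracle", {
  d <- c(-0.01, 0.00, 0.01, 0.02)
  x <- 1:4 + d; y <- 1:4
  ba <- blandAltman(x, y)
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$sdDiff, sqrt(sum((d - mean(d))^2) / 3))
  expect_equal(ba$loaHigh - ba$loaLow, 2 * 1.96 * ba$sdDiff)
  expect_equal(ba$loaLow, ba$bias - 1.96 * ba$sdDiff)
  ident <- blandAltman(y, y)
  expect_equal(ident$bias, 0)
  expect_equal(ident$loaHigh, 0)
  off <- blandAltman(y + 0.01, y)
  expect_equal(off$bias, 0.01)
  expect_equal(off$sdDiff, 0)
  expect_error(blandAltman(1, 1), "2 pairs")
  expect_error(blandAltman(1:3, 1:4), "equal length")
})

test_that("AUC equals the brute-force Mann-Whitney U probability", {
  expect_equal(rocAuc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(rocAuc(rep(0.4, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  set.seed(31)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s <- round(rnorm(n), sample(0:2, 1))          # rounding induces ties
    expect_equal(rocAuc(s, y), bruteAuc(s, y), tolerance = 1e-12)
  }
  expect_error(rocAuc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  y <- rbinom(60, 1, 0.3)
  s <- rnorm(60) + y
  expect_equal(rocAuc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("Youden operating point matches the exhaustive threshold sweep", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(10:100, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.3))
    s <- y + rnorm(n) * 0.8
    flip <- sample(n, round(0.1 * n))
    s[flip] <- -s[flip]
    got <- youdenOperatingPoint(s, y)
    want <- bruteYouden(s, y)
    expect_equal(got$j, want$j, tolerance = 1e-12)
    expect_equal(got$sensitivity + got$specificity - 1, got$j)
  }
  perf <- youdenOperatingPoint(c(1, 2, 8, 9), c(0, 0, 1, 1))
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)
  deg <- youdenOperatingPoint(rep(1, 5), c(0, 1, 0, 1, 1))
  expect_equal(deg$j, 0)
})

test_that("stratified k-fold partitions are proportional, disjoint, seeded", {
  y <- rep(c(0, 1), c(80, 20))
  folds <- stratifiedKfold(y, 5, seed = 3)
  expect_length(folds, 5)
  tests <- lapply(folds, `[[`, "test")
  expect_setequal(unlist(tests), seq_along(y))
  expect_equal(sum(vapply(tests, length, 1L)), 100L)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_equal(sum(y[f$test] == 1), 4)          # 20 positives over 5 folds
  }
  expect_identical(stratifiedKfold(y, 5, seed = 3), folds)
  expect_error(stratifiedKfold(rep(c(0, 1), c(98, 2)), 5), "at least k")
})

test_that("independent t-test matches the textbook formula and handles ties", {
  a <- c(5.1, 4.8, 5.6, 5.0, 4.9)
  b <- c(4.2, 4.5, 4.1, 4.4, 4.0)
  got <- independentTTest(a, b, varEqual = TRUE)
  sp <- sqrt(((4 * var(a)) + (4 * var(b))) / 8)
  tOracle <- (mean(a) - mean(b)) / (sp * sqrt(2 / 5))
  expect_equal(got$t, tOracle, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(tOracle), df = 8), tolerance = 1e-12)
  same <- independentTTest(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  set.seed(2)
  big <- independentTTest(rnorm(50), rnorm(50) + 2)
  expect_lt(big$p, 0.05)
  expect_error(independentTTest(1, 1:3), "at least 2")
})
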