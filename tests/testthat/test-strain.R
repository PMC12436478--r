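test_that("contour length matches closed forms for simple polylines", {
  expect_equal(contourLength(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))), 4)
  expect_equal(contourLength(cbind(c(0, 3, 0), c(0, 0, 4))), 12)  # 3-4-5
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  poly <- cbind(10 * cos(th), 10 * sin(th))       # regular 360-gon, r = 10
  expect_lt(abs(contourLength(poly) - 2 * pi * 10) / (2 * pi * 10), 0.001)
  expect_error(contourLength(cbind(0:1, 0:1)), "3 vertices")
})

test_that("extracted perimeter of a rasterized disc is within 2% of 2*pi*r", {
  m <- discMask(r = 50)
  v <- extractContour(m)
  expect_lt(abs(contourLength(v) - 2 * pi * 50) / (2 * pi * 50), 0.02)
})

test_that("contour extraction follows the largest-component rule", {
  m <- discMask(r = 18, sz = 96, cx = 40, cy = 40)
  m[85:87, 85:89] <- 1L                           # 15-px second blob
  v <- extractContour(m)
  expect_true(all(v[, 1] < 70))                   # contour hugs the big disc
  expect_error(extractContour(matrix(0L, 8, 8)), "empty cavity")
})

test_that("base frame selection honours the R peak and the min-length rule", {
  expect_identical(selectBaseFrame(c(120, 100, 110), rPeakIndex = 3), 3L)
  expect_identical(selectBaseFrame(c(120, 100, 110)), 2L)
  expect_identical(selectBaseFrame(rep(5, 4)), 1L)       # tie -> earliest
  expect_error(selectBaseFrame(c(1, 2), rPeakIndex = 5), "out of range")
})

test_that("strain formula (L_t - L_0)/L_0 is applied exactly", {
  sc <- strainCurve(c(100, 110, 105), 1)
  expect_equal(strainValues(sc), c(0, 0.10, 0.05))
  expect_equal(strainValues(strainCurve(rep(80, 5), 2)), rep(0, 5))
  expect_equal(strainValues(strainCurve(c(100, 80), 1)), c(0, -0.20))
  expect_error(strainCurve(c(0, 10), 1), "positive")
})

test_that("equidistant resampling picks round(i(T-1)/(m-1)) with endpoints", {
  expect_equal(resampleEquidistant(1:30, 30), 1:30)       # identity
  expect_equal(resampleEquidistant(1:59, 30), seq(1, 59, by = 2))
  expect_error(resampleEquidistant(1:10, 30), "insufficient frames")
  sc <- strainCurve(seq(100, 129), 1)
  rs <- resampleEquidistant(sc)
  expect_true(rs@isResampled)
  expect_length(strainValues(rs), 30)
})

test_that("peak strain is the maximum over timestamps", {
  expect_equal(peakStrain(c(0, 0.10, 0.05)), 0.10)
  expect_equal(peakStrain(rep(0, 4)), 0)
  expect_error(peakStrain(numeric(0)), "empty")
})

test_that("ground-truth phantom masks reproduce the analytic strain curve", {
  ph <- smallPhantom()
  sc <- sequenceToStrain(ph$masks, rPeakIndex = 1L, resample = FALSE)
  expect_lt(max(abs(strainValues(sc) - ph$truth@trueStrain)), 0.01)
  expect_equal(strainValues(sc)[1], 0)
})

test_that("strain is invariant to uniform mask scaling", {
  ## render the same geometry at two sizes: strain curves must agree
  a <- makePhantom(phantomParams(size = 128, nframes = 6, wallThickness = 2,
                                 sMax = 1.18), seed = 5)
  b <- makePhantom(phantomParams(size = 224, nframes = 6, wallThickness = 3,
                                 sMax = 1.18), seed = 5)
  sa <- strainValues(sequenceToStrain(a$masks, 1L, resample = FALSE))
  sb <- strainValues(sequenceToStrain(b$masks, 1L, resample = FALSE))
  expect_lt(max(abs(sa - sb)), 0.01)
})

test_that("a frame without cavity pixels is reported by index", {
  ph <- smallPhantom()
  ms <- masks(ph$masks)
  ms[[3]][ms[[3]] == 1L] <- 0L
  expect_error(sequenceToStrain(ms, 1L), "frame 3")
})

test_that("constant masks give a zero strain curve", {
  m <- discMask(r = 30, sz = 96)
  sc <- sequenceToStrain(rep(list(m), 6), resample = FALSE)
  expect_equal(strainValues(sc), rep(0, 6))
})
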