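test_that("an empty cohort request returns the empty schema", {
  co <- simulateCohort(0)
  expect_equal(nrow(co), 0L)
  expect_true(all(c("id", "age", "sex", "peak_strain", "strain_t29") %in%
                    names(co)))
  expect_error(simulateCohort(-1), "non-negative")
})

test_that("cohort simulation is reproducible and labels match groups", {
  a <- simulateCohort(200, seed = 5)
  b <- simulateCohort(200, seed = 5)
  expect_identical(a, b)
  ## threshold labels are consistent with group assignment by construction
  lab6 <- thresholdLabel(a$ahre_minutes, "6min")
  expect_true(all(lab6[a$ahre_group == "ahre_lt_6min"] == 0))
  expect_true(all(lab6[a$ahre_group != "ahre_lt_6min"] == 1))
  lab24 <- thresholdLabel(a$ahre_minutes, "24h")
  expect_true(all(lab24 == (a$ahre_group == "ahre_ge_24h")))
})

test_that("cohort marginals calibrate to the specification at n = 2000", {
  co <- simulateCohort(2000, seed = 31)
  spec <- cohortSpec()
  ## group proportions within 3 SE of the multinomial expectation
  for (g in 1:3) {
    p <- spec$probs[g]
    se <- sqrt(p * (1 - p) / 2000)
    expect_lt(abs(mean(as.integer(co$ahre_group) == g) - p), 3 * se)
  }
  ## per-group peak strain means within 3 SE of the group targets
  for (g in 1:3) {
    x <- 100 * co$peak_strain[as.integer(co$ahre_group) == g]
    se <- spec$strainPct[2, g] / sqrt(length(x))
    expect_lt(abs(mean(x) - spec$strainPct[1, g]), 3 * se)
  }
  expect_true(all(co$ahre_burden_pct >= 0 & co$ahre_burden_pct <= 100))
  expect_true(all(co$chads_vasc %in% 0:9))
  expect_true(all(co$ahre_minutes >= 0))
})

test_that("strain curves start at zero and peak exactly at the drawn peak", {
  v <- strainCurveFromPeak(0.25, noiseSd = 0)
  expect_length(v, 30)
  expect_equal(v[1], 0)
  expect_equal(max(v), 0.25)
  vz <- strainCurveFromPeak(0, noiseSd = 0.005, seed = 2)
  expect_true(all(vz <= 0))
  expect_equal(max(vz), 0)
  vn <- strainCurveFromPeak(0.3, noiseSd = 0.01, seed = 3)
  expect_equal(max(vn), 0.3)    # noise is clipped at the peak
  expect_error(strainCurveFromPeak(0.2, T = 1), "at least 2")
  co <- simulateCohort(50, seed = 8)
  expect_equal(apply(co[, sprintf("strain_t%02d", 0:29)], 1, max),
               co$peak_strain, tolerance = 1e-12)
})

test_that("summary table combines group columns by patient-count weighting", {
  co <- simulateCohort(300, seed = 12)
  s <- summarizeCohort(co)
  expect_equal(sum(s$n), 300L)
  ## overall mean = weighted average of group means, for every continuous var
  for (v in names(s$continuous)) {
    m <- s$continuous[[v]]
    expect_equal(m["mean", "overall"],
                 combineGroupMeans(m["mean", -1], s$n), tolerance = 1e-12)
  }
  ## binary counts add
  for (v in names(s$binary))
    expect_equal(s$binary[[v]]["count", "overall"],
                 sum(s$binary[[v]]["count", -1]))
  expect_error(summarizeCohort(simulateCohort(0)), "empty")
})

test_that("one-patient cohort's overall column equals its group column", {
  co <- simulateCohort(1, seed = 3)
  s <- summarizeCohort(co)
  g <- as.character(co$ahre_group[1])
  m <- s$continuous$age
  expect_equal(m["mean", "overall"], m["mean", g])
})

test_that("spec validation rejects malformed settings", {
  expect_error(cohortSpec(probs = c(0.5, 0.4, 0.2)), "sum to 1")
  bad <- rbind(c(1, 1, 1), c(0, 1, 1))
  expect_error(cohortSpec(age = bad), "SDs")
})

test_that("cohort CSV round-trips through the exact column schema", {
  co <- simulateCohort(25, seed = 4)
  f <- tempfile(fileext = ".csv")
  writeCohortCsv(co, f)
  back <- readCohortCsv(f)
  expect_equal(back$peak_strain, co$peak_strain, tolerance = 1e-12)
  expect_identical(as.character(back$ahre_group), as.character(co$ahre_group))
  expect_identical(names(back)[1:14],
                   c("id", "age", "sex", "bmi", "bsa", "chads_vasc", "mi",
                     "cad", "thyroid", "dm", "htn", "ahre_minutes",
                     "ahre_burden_pct", "peak_strain"))
})
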