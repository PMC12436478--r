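## QC flags are exercised on constructed fixtures at a reduced image size to
## keep the unit suite fast; the acceptance suite repeats this over many
## seeds.

test_that("each fixture kind violates exactly its own criterion", {
  ph <- makePhantom(phantomParams(nframes = 1), seed = 3)
  img <- frames(ph$sequence)[[1]]
  msk <- masks(ph$masks)[[1]]
  cleanFlags <- qcFlags(img, msk)
  expect_false(cleanFlags$excluded)                      # negative control
  for (kind in fixtureKinds()) {
    fx <- makeFixture(kind, seed = 4)
    r <- qcFlags(frames(fx$sequence)[[1]], masks(fx$masks)[[1]])
    want <- c(single_chamber = "flag_a", truncated_bottom = "flag_b",
              beyond_sector = "flag_c", blurred_boundary = "flag_d",
              black_region = "flag_e")[[kind]]
    hit <- names(r)[1:5][unlist(r[1:5])]
    expect_identical(hit, want)
  }
  expect_error(makeFixture("nonsense"), "arg")
})

test_that("fixture constructions meet their quantitative definitions", {
  fb <- makeFixture("truncated_bottom", seed = 6)
  mb <- masks(fb$masks)[[1]]
  runs <- rle(mb[nrow(mb), ] == 1L)
  expect_gte(max(runs$lengths[runs$values]), 20)
  fe <- makeFixture("black_region", seed = 6)
  ie <- frames(fe$sequence)[[1]]; me <- masks(fe$masks)[[1]]
  expect_gte(mean(ie[me == 1L] < 0.05), 0.10)
  fc <- makeFixture("beyond_sector", seed = 6)
  ic <- frames(fc$sequence)[[1]]; mc <- masks(fc$masks)[[1]]
  out <- sum(mc > 0 & !sectorSupport(ic)) / sum(mc > 0)
  expect_gte(out, 0.05)
})

test_that("single-chamber detection reacts to the second blood pool", {
  ph <- makePhantom(phantomParams(nframes = 1), seed = 9)
  img <- frames(ph$sequence)[[1]]
  msk <- masks(ph$masks)[[1]]
  expect_false(checkSingleChamber(img, msk))             # LV present
  noLv <- makePhantom(phantomParams(nframes = 1, renderLv = FALSE), seed = 9)
  expect_true(checkSingleChamber(frames(noLv$sequence)[[1]],
                                 masks(noLv$masks)[[1]]))
  ## all-tissue image: no dark region anywhere
  flat <- matrix(0.6, nrow(img), ncol(img))
  expect_true(checkSingleChamber(flat, msk))
  expect_error(checkSingleChamber(img, msk * 0L), "empty mask")
})

test_that("boundary-gradient flag fires on gradient-free images", {
  ph <- makePhantom(phantomParams(nframes = 1), seed = 10)
  msk <- masks(ph$masks)[[1]]
  uniform <- matrix(0.5, nrow(msk), ncol(msk))
  expect_true(checkBlurredBoundary(uniform, msk))
  expect_false(checkBlurredBoundary(frames(ph$sequence)[[1]], msk))
})

test_that("a normal dark blood pool does not raise the black-region flag", {
  ph <- makePhantom(phantomParams(nframes = 1), seed = 12)
  expect_false(checkBlackRegion(frames(ph$sequence)[[1]],
                                masks(ph$masks)[[1]]))
})

test_that("mask truncation threshold is respected at the boundary", {
  m <- matrix(0L, 50, 50)
  m[30:50, 20:30] <- 1L
  m[50, ] <- 0L
  m[50, 21:29] <- 1L                       # 9 touching pixels < default 20
  expect_false(checkTruncatedBottom(m))
  m[50, 10:40] <- 1L                       # 31 consecutive
  expect_true(checkTruncatedBottom(m))
})

test_that("exclusion filtering keeps clean frames, drops fixtures, idempotent", {
  cleanPh <- makePhantom(phantomParams(size = 160, nframes = 6), seed = 21)
  dataset <- lapply(1:6, function(t)
    list(image = frames(cleanPh$sequence)[[t]],
         mask = masks(cleanPh$masks)[[t]], id = sprintf("clean%02d", t)))
  for (kind in fixtureKinds()) {
    fx <- makeFixture(kind, seed = 22, size = 160)
    dataset[[length(dataset) + 1]] <- list(
      image = frames(fx$sequence)[[1]], mask = masks(fx$masks)[[1]], id = kind)
  }
  res <- applyExclusions(dataset)
  expect_length(res$clean, 6)
  expect_setequal(res$report$id[res$report$excluded], fixtureKinds())
  ## idempotence: re-filtering the clean subset excludes nothing
  res2 <- applyExclusions(res$clean)
  expect_length(res2$clean, 6)
  ## all-fixture input -> empty subset
  res3 <- applyExclusions(dataset[7:11])
  expect_length(res3$clean, 0)
  expect_error(applyExclusions(list()), "empty dataset")
})
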