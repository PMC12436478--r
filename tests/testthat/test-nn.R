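## The training engine: analytic gradients are verified against central
## differences on tiny problems, and the losses against direct-summation
## oracles.

es <- asNamespace("echostrain")

test_that("convolution gradients match numerical differentiation", {
  set.seed(1)
  H <- 5L; W <- 4L; N <- 2L; Cin <- 3L; Cout <- 2L; k <- 3L
  x0 <- matrix(rnorm(Cin * H * W * N), Cin)
  W0 <- matrix(rnorm(Cout * Cin * k * k), Cout)
  b0 <- rnorm(Cout)
  run <- function(xv, Wv, bv, stride, dil) {
    tp <- es$tapeNew()
    xn <- es$tapeParam(tp, xv); Wn <- es$tapeParam(tp, Wv)
    bn <- es$tapeParam(tp, bv)
    y <- es$opConv(tp, xn, Wn, bn, H, W, N, k, stride, dil)
    l <- es$tapeAdd(tp, sum(y$val^2), list(y), function(g) list(2 * g * y$val))
    es$tapeBackward(tp, l)
    list(val = l$val, gx = xn$grad, gW = Wn$grad, gb = bn$grad)
  }
  for (sd in list(c(1L, 1L), c(2L, 1L), c(1L, 2L))) {
    r <- run(x0, W0, b0, sd[1], sd[2])
    expect_equal(r$gx, numGrad(function(v) run(v, W0, b0, sd[1], sd[2])$val, x0),
                 tolerance = 1e-6)
    expect_equal(r$gW, numGrad(function(v) run(x0, v, b0, sd[1], sd[2])$val, W0),
                 tolerance = 1e-6)
    expect_equal(r$gb, numGrad(function(v) run(x0, W0, v, sd[1], sd[2])$val, b0),
                 tolerance = 1e-6)
  }
})

test_that("group norm, attention and layer norm gradients are exact", {
  set.seed(2)
  ## group norm
  C <- 4L; HW <- 6L; N <- 2L
  x0 <- matrix(rnorm(C * HW * N), C)
  g0 <- runif(C, 0.5, 1.5); b0 <- rnorm(C)
  w <- matrix(seq_len(C * HW * N), C)
  gn <- function(xv) {
    tp <- es$tapeNew()
    xn <- es$tapeParam(tp, xv)
    y <- es$opGroupNorm(tp, xn, es$tapeConst(tp, g0), es$tapeConst(tp, b0),
                        2L, HW, N)
    l <- es$tapeAdd(tp, sum(y$val * w), list(y), function(g) list(g * w))
    es$tapeBackward(tp, l)
    list(val = l$val, gx = xn$grad)
  }
  expect_equal(gn(x0)$gx, numGrad(function(v) gn(v)$val, x0), tolerance = 1e-5)
  ## attention
  d <- 6L; Tn <- 4L; B <- 2L
  Q0 <- matrix(rnorm(d * Tn * B), d); K0 <- Q0 * 0.5 + 1; V0 <- Q0 - 0.3
  wA <- matrix(rnorm(d * Tn * B), d)
  at <- function(Qv) {
    tp <- es$tapeNew()
    Qn <- es$tapeParam(tp, Qv)
    y <- es$opAttention(tp, Qn, es$tapeConst(tp, K0), es$tapeConst(tp, V0),
                        Tn, B, 2L)
    l <- es$tapeAdd(tp, sum(y$val * wA), list(y), function(g) list(g * wA))
    es$tapeBackward(tp, l)
    list(val = l$val, gQ = Qn$grad)
  }
  expect_equal(at(Q0)$gQ, numGrad(function(v) at(v)$val, Q0), tolerance = 1e-5)
  ## layer norm
  x1 <- matrix(rnorm(5 * 4), 5)
  wL <- matrix(rnorm(20), 5)
  ln <- function(xv) {
    tp <- es$tapeNew()
    xn <- es$tapeParam(tp, xv)
    y <- es$opLayerNorm(tp, xn, es$tapeConst(tp, rep(1, 5)),
                        es$tapeConst(tp, rep(0, 5)))
    l <- es$tapeAdd(tp, sum(y$val * wL), list(y), function(g) list(g * wL))
    es$tapeBackward(tp, l)
    list(val = l$val, gx = xn$grad)
  }
  expect_equal(ln(x1)$gx, numGrad(function(v) ln(v)$val, x1), tolerance = 1e-5)
})

test_that("soft Dice + CE agrees with a direct-summation oracle", {
  ## uniform probability 1/3, single-class target on N pixels
  Np <- 12L
  prob <- matrix(1 / 3, 3, Np)
  target <- rep(1L, Np)                   # class "cavity" everywhere (label 1)
  eps <- 1e-6
  ## direct 10-line oracle
  oracle <- local({
    C <- 3; tot <- 0
    tmat <- matrix(0, C, Np); tmat[cbind(target + 1L, seq_len(Np))] <- 1
    for (c in seq_len(C)) {
      num <- 2 * sum(prob[c, ] * tmat[c, ]) + eps
      den <- sum(prob[c, ]) + sum(tmat[c, ]) + eps
      tot <- tot + (1 - num / den)
    }
    tot / C - mean(log(prob[cbind(target + 1L, seq_len(Np))]))
  })
  expect_equal(softDiceCeLoss(prob, target), oracle, tolerance = 1e-12)
})

test_that("loss is ~zero on one-hot truth and large on wrong predictions", {
  target <- matrix(c(0L, 1L, 2L, 1L), 2)
  onehot <- matrix(0, 3, 4)
  onehot[cbind(as.vector(target) + 1L, 1:4)] <- 1
  eps <- 1e-7
  good <- softDiceCeLoss(pmin(pmax(onehot, eps), 1 - eps) /
                           rep(colSums(pmin(pmax(onehot, eps), 1 - eps)),
                               each = 3), target)
  expect_lt(good, 1e-4)
  wrong <- onehot[c(2, 3, 1), ]            # rotate classes: all wrong
  bad <- softDiceCeLoss(pmin(pmax(wrong, eps), 1 - eps) /
                          rep(colSums(pmin(pmax(wrong, eps), 1 - eps)),
                              each = 3), target)
  expect_gt(bad, good)
  expect_gt(bad, 1)                        # Dice term ~1 per present class
  expect_error(softDiceCeLoss(matrix(0.5, 3, 4), target), "sum to 1")
})

test_that("cosine annealing runs from lr0 to zero", {
  expect_equal(cosineAnnealLr(0, 400), 0.001)
  expect_equal(cosineAnnealLr(399, 400), 0)
  expect_equal(cosineAnnealLr(100, 201), 0.0005)   # midpoint
  lrs <- vapply(0:19, cosineAnnealLr, numeric(1), epochs = 20)
  expect_true(all(diff(lrs) < 0))
})

test_that("weighted BCE has its closed-form values and plain-BCE limit", {
  expect_equal(weightedBce(0.5, 1, 2), 2 * log(2))
  expect_equal(weightedBce(0.5, 0, 7), log(2))     # weight only on positives
  set.seed(3)
  p <- runif(20, 0.01, 0.99); y <- rbinom(20, 1, 0.5)
  expect_equal(weightedBce(p, y, 1), -(y * log(p) + (1 - y) * log(1 - p)))
  expect_error(weightedBce(1, 1, 1), "strictly")
  expect_error(weightedBce(0.5, 1, 0), "positive")
})

test_that("imbalance weight equals negatives over positives", {
  expect_equal(autoPosWeight(rep(c(0, 1), c(90, 10))), 9)
  expect_equal(autoPosWeight(c(0, 1, 0, 1)), 1)
  expect_equal(autoPosWeight(rep(c(0, 1), c(104, 13))), 8)
  expect_error(autoPosWeight(rep(1, 5)), "both classes")
})
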