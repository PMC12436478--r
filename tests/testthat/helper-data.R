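## Shared small fixtures, built once per test run.

## a small clean phantom used by several files (160 px, 8 frames; strain
## extraction needs cavities tens of pixels across for sub-percent accuracy)
smallPhantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- makePhantom(phantomParams(size = 160, nframes = 8,
                                          wallThickness = 2, sMax = 1.2),
                            seed = 11)
    cache
  }
})

## a filled disc mask (cavity label 1) of radius r in a sz x sz grid
discMask <- function(r = 50, sz = 160, cx = sz / 2 + 0.3, cy = sz / 2 + 0.7) {
  xx <- matrix(rep(seq_len(sz), each = sz), sz)
  yy <- t(xx)
  m <- matrix(0L, sz, sz)
  m[(xx - cx)^2 + (yy - cy)^2 <= r^2] <- 1L
  m
}

## brute-force AUC over all positive x negative pairs (ties count 1/2)
bruteAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

## exhaustive Youden sweep over every possible threshold (including +/- Inf)
bruteYouden <- function(scores, labels) {
  cand <- c(-Inf, sort(unique(scores)), Inf)
  best <- list(j = -Inf)
  for (thr in cand) {
    pred <- as.integer(scores >= thr)
    sens <- sum(pred & labels) / sum(labels)
    spec <- sum(!pred & !labels) / sum(!labels)
    if (sens + spec - 1 > best$j + 1e-12)
      best <- list(j = sens + spec - 1, sensitivity = sens, specificity = spec)
  }
  best
}

## tiny numeric gradient
numGrad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
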