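## Minimal reverse-mode automatic differentiation tape.
##
## Every differentiable quantity is a node: an environment holding the forward
## value (`val`), an accumulated gradient (`grad`), the parent nodes, and a
## backward closure mapping the node's output gradient to a list of parent
## gradients. Nodes are appended to a tape in creation order; backpropagation
## walks the tape in reverse. Feature maps are (C x H*W*N) matrices with the
## pixel index running h fastest, then w, then sample; sequence activations
## are (d x T*B) matrices with the token index fastest. Shape bookkeeping
## lives in the network builders, keeping the ops generic on matrices.

tapeNew <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tapeAdd <- function(tp, val, parents = list(), bw = NULL, const = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$bw <- bw
  nd$const <- const
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[tp$n]] <- nd
  nd
}

tapeConst <- function(tp, val) tapeAdd(tp, val, const = TRUE)
tapeParam <- function(tp, val) tapeAdd(tp, val)

.accum <- function(nd, g) {
  if (is.null(g) || isTRUE(nd$const)) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

tapeBackward <- function(tp, loss) {
  stopifnot(length(loss$val) == 1L)
  loss$grad <- 1
  for (i in seq(tp$n, 1L)) {
    nd <- tp$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$bw)) next
    gs <- nd$bw(nd$grad)
    for (j in seq_along(gs)) .accum(nd$parents[[j]], gs[[j]])
  }
  invisible(NULL)
}

## ---- generic matrix ops ----------------------------------------------------

opAdd <- function(tp, a, b) {
  tapeAdd(tp, a$val + b$val, list(a, b), function(g) list(g, g))
}

opRelu <- function(tp, a) {
  m <- a$val > 0
  tapeAdd(tp, a$val * m, list(a), function(g) list(g * m))
}

opSigmoid <- function(tp, a) {
  s <- 1 / (1 + exp(-a$val))
  tapeAdd(tp, s, list(a), function(g) list(g * s * (1 - s)))
}

## y = W x + b with W (Cout x Cin), x (Cin x M), b length Cout
opDense <- function(tp, W, x, b = NULL) {
  y <- W$val %*% x$val
  if (!is.null(b)) y <- y + b$val
  parents <- if (is.null(b)) list(W, x) else list(W, x, b)
  xv <- x$val
  Wv <- W$val
  tapeAdd(tp, y, parents, function(g) {
    out <- list(g %*% t(xv), crossprod(Wv, g))
    if (!is.null(b)) out[[3]] <- rowSums(g)
    out
  })
}

opDropout <- function(tp, a, rate, training) {
  if (!training || rate <= 0) return(a)
  m <- (matrix(stats::runif(length(a$val)), nrow(a$val)) >= rate) / (1 - rate)
  tapeAdd(tp, a$val * m, list(a), function(g) list(g * m))
}

opConcatRows <- function(tp, a, b) {
  na <- nrow(a$val)
  tapeAdd(tp, rbind(a$val, b$val), list(a, b), function(g) {
    list(g[seq_len(na), , drop = FALSE], g[-seq_len(na), , drop = FALSE])
  })
}

## ---- convolution-side ops --------------------------------------------------

opConv <- function(tp, x, W, b, H, Wd, N, k, stride = 1L, dil = 1L) {
  onebyone <- k == 1L && stride == 1L          # pointwise: no unrolling needed
  cols <- if (onebyone) x$val
          else im2col_cpp(x$val, H, Wd, N, k, stride, dil)
  y <- W$val %*% cols + b$val
  C <- nrow(x$val)
  Wv <- W$val
  needDx <- !isTRUE(x$const)
  tapeAdd(tp, y, list(x, W, b), function(g) {
    dx <- if (!needDx) NULL
    else if (onebyone) crossprod(Wv, g)
    else col2im_cpp(crossprod(Wv, g), C, H, Wd, N, k, stride, dil)
    list(dx, tcrossprod(g, cols), rowSums(g))
  })
}

## Group normalization over (channel-group x all pixels) per sample.
opGroupNorm <- function(tp, x, gamma, beta, groups, HW, N, eps = 1e-5) {
  C <- nrow(x$val)
  stopifnot(C %% groups == 0L)
  cg <- C / groups
  xhat <- x$val
  sig <- matrix(0, groups, N)
  for (n in seq_len(N)) {
    cols <- ((n - 1L) * HW + 1L):(n * HW)
    for (g in seq_len(groups)) {
      rows <- ((g - 1L) * cg + 1L):(g * cg)
      v <- x$val[rows, cols]
      mu <- mean(v)
      s <- sqrt(mean((v - mu)^2) + eps)
      sig[g, n] <- s
      xhat[rows, cols] <- (v - mu) / s
    }
  }
  y <- xhat * gamma$val + beta$val   # gamma/beta recycled along columns (C vectors)
  gv <- gamma$val
  tapeAdd(tp, y, list(x, gamma, beta), function(gr) {
    dx <- xhat
    gxh <- gr * gv
    for (n in seq_len(N)) {
      cols <- ((n - 1L) * HW + 1L):(n * HW)
      for (g in seq_len(groups)) {
        rows <- ((g - 1L) * cg + 1L):(g * cg)
        gi <- gxh[rows, cols]
        xh <- xhat[rows, cols]
        dx[rows, cols] <- (gi - mean(gi) - xh * mean(gi * xh)) / sig[g, n]
      }
    }
    list(dx, rowSums(gr * xhat), rowSums(gr))
  })
}

opGlobalAvgPool <- function(tp, x, HW, N) {
  C <- nrow(x$val)
  y <- matrix(0, C, N)
  for (n in seq_len(N)) y[, n] <- rowMeans(x$val[, ((n - 1L) * HW + 1L):(n * HW), drop = FALSE])
  tapeAdd(tp, y, list(x), function(g) {
    list(g[, rep(seq_len(N), each = HW), drop = FALSE] / HW)
  })
}

## Per-channel, per-sample scaling (squeeze-excitation): s is (C x N).
opChannelScale <- function(tp, x, s, HW, N) {
  idx <- rep(seq_len(N), each = HW)
  sexp <- s$val[, idx, drop = FALSE]
  xv <- x$val
  tapeAdd(tp, xv * sexp, list(x, s), function(g) {
    ds <- t(rowsum(t(g * xv), group = idx))
    dimnames(ds) <- NULL
    list(g * sexp, ds)
  })
}

## Spatial (per-pixel) gating: gate is a (1 x M) node broadcast over channels.
opSpatialScale <- function(tp, x, gate) {
  C <- nrow(x$val)
  gexp <- gate$val[rep(1L, C), , drop = FALSE]
  xv <- x$val
  tapeAdd(tp, xv * gexp, list(x, gate), function(g) {
    list(g * gexp, matrix(colSums(g * xv), nrow = 1L))
  })
}

## Nearest-neighbour 2x upsampling of (C x H*W*N) maps.
opUpsample2 <- function(tp, x, H, W, N) {
  H2 <- 2L * H; W2 <- 2L * W
  hi <- (seq_len(H2) + 1L) %/% 2L
  wi <- (seq_len(W2) + 1L) %/% 2L
  src <- as.vector(outer(hi, (wi - 1L) * H, `+`))          # H2*W2 map into one frame
  idx <- as.vector(outer(src, (seq_len(N) - 1L) * H * W, `+`))
  tapeAdd(tp, x$val[, idx, drop = FALSE], list(x), function(g) {
    dx <- t(rowsum(t(g), group = idx))
    dimnames(dx) <- NULL
    # rowsum orders groups by sorted unique index = 1..H*W*N (all present)
    list(dx)
  })
}

## Fused softmax + (soft Dice + cross-entropy) loss over a pixel batch.
## logits: (C x M) node; target: integer vector length M with labels 1..C.
opDiceCeLoss <- function(tp, logits, target, eps = 1e-6) {
  z <- logits$val
  C <- nrow(z); M <- ncol(z)
  cm <- do.call(pmax, lapply(seq_len(C), function(i) z[i, ]))  # colwise max
  z <- z - rep(cm, each = C)
  ez <- exp(z)
  p <- ez / rep(colSums(ez), each = C)
  Tm <- matrix(0, C, M)
  Tm[cbind(target, seq_len(M))] <- 1
  Sc <- rowSums(p * Tm); Pc <- rowSums(p); Tc <- rowSums(Tm)
  dice <- mean(1 - (2 * Sc + eps) / (Pc + Tc + eps))
  ce <- -mean(log(pmax(p[cbind(target, seq_len(M))], 1e-12)))
  denom <- Pc + Tc + eps
  Gd <- -(2 * Tm * denom - (2 * Sc + eps)) / denom^2 / C   # dL_dice/dp
  tapeAdd(tp, dice + ce, list(logits), function(g) {
    dz_ce <- (p - Tm) / M
    dz_d <- p * (Gd - rep(colSums(Gd * p), each = C))
    list(g * (dz_ce + dz_d))
  })
}

## Fused weighted binary cross-entropy on logits z (1 x B), labels y in {0,1}.
opWeightedBceLoss <- function(tp, z, y, wPos) {
  zv <- as.vector(z$val)
  B <- length(zv)
  sp <- function(u) ifelse(u > 30, u, log1p(exp(u)))      # softplus, overflow-safe
  loss <- mean(wPos * y * sp(-zv) + (1 - y) * sp(zv))
  s <- 1 / (1 + exp(-zv))
  tapeAdd(tp, loss, list(z), function(g) {
    list(matrix(g * ((1 - y) * s - wPos * y * (1 - s)) / B, nrow = 1L))
  })
}

## ---- sequence-side ops (transformer) --------------------------------------

## Column-wise layer normalization of (d x M) activations.
opLayerNorm <- function(tp, x, gamma, beta, eps = 1e-5) {
  d <- nrow(x$val)
  mu <- colMeans(x$val)
  xc <- x$val - rep(mu, each = d)
  sig <- sqrt(colMeans(xc^2) + eps)
  xhat <- xc / rep(sig, each = d)
  gv <- gamma$val
  tapeAdd(tp, xhat * gv + beta$val, list(x, gamma, beta), function(g) {
    gxh <- g * gv
    dx <- (gxh - rep(colMeans(gxh), each = d) -
             xhat * rep(colMeans(gxh * xhat), each = d)) / rep(sig, each = d)
    list(dx, rowSums(g * xhat), rowSums(g))
  })
}

## Batched multi-head scaled dot-product self-attention. Q, K, V are
## (d x T*B) nodes (token index fastest); d = heads * dh.
opAttention <- function(tp, Q, K, V, Tn, B, heads) {
  d <- nrow(Q$val)
  stopifnot(d %% heads == 0L)
  dh <- d / heads
  Z <- matrix(0, d, Tn * B)
  A <- vector("list", B * heads)           # cached softmax matrices (T x T)
  for (n in seq_len(B)) {
    cols <- ((n - 1L) * Tn + 1L):(n * Tn)
    for (h in seq_len(heads)) {
      rows <- ((h - 1L) * dh + 1L):(h * dh)
      Qh <- Q$val[rows, cols, drop = FALSE]
      Kh <- K$val[rows, cols, drop = FALSE]
      S <- crossprod(Kh, Qh) / sqrt(dh)    # S[i,j] = k_i . q_j
      S <- S - max(S)                      # global shift suffices for stability
      eS <- exp(S)
      Ah <- eS / rep(colSums(eS), each = Tn)
      A[[(n - 1L) * heads + h]] <- Ah
      Z[rows, cols] <- V$val[rows, cols, drop = FALSE] %*% Ah
    }
  }
  Qv <- Q$val; Kv <- K$val; Vv <- V$val
  tapeAdd(tp, Z, list(Q, K, V), function(g) {
    dQ <- matrix(0, d, Tn * B); dK <- dQ; dV <- dQ
    for (n in seq_len(B)) {
      cols <- ((n - 1L) * Tn + 1L):(n * Tn)
      for (h in seq_len(heads)) {
        rows <- ((h - 1L) * dh + 1L):(h * dh)
        Ah <- A[[(n - 1L) * heads + h]]
        gZ <- g[rows, cols, drop = FALSE]
        Vh <- Vv[rows, cols, drop = FALSE]
        dV[rows, cols] <- tcrossprod(gZ, Ah)
        dA <- crossprod(Vh, gZ)                       # T x T
        dS <- Ah * (dA - rep(colSums(dA * Ah), each = Tn)) / sqrt(dh)
        dQ[rows, cols] <- Kv[rows, cols, drop = FALSE] %*% dS
        dK[rows, cols] <- tcrossprod(Qv[rows, cols, drop = FALSE], dS)
      }
    }
    list(dQ, dK, dV)
  })
}

## Prepend a per-sample summary token to a (d x T*B) token sequence,
## giving (d x (T+1)*B).
opPrependToken <- function(tp, tok, seqn, Tn, B) {
  d <- nrow(seqn$val)
  T1 <- Tn + 1L
  out <- matrix(0, d, T1 * B)
  tokCols <- (seq_len(B) - 1L) * T1 + 1L
  seqCols <- setdiff(seq_len(T1 * B), tokCols)
  out[, tokCols] <- tok$val
  out[, seqCols] <- seqn$val
  tapeAdd(tp, out, list(tok, seqn), function(g) {
    list(g[, tokCols, drop = FALSE], g[, seqCols, drop = FALSE])
  })
}

## Select one token column per sample from (d x T*B): used to pool the
## summary token. tokenIdx is 1-based within each sample block.
opSelectToken <- function(tp, x, Tn, B, tokenIdx = 1L) {
  idx <- (seq_len(B) - 1L) * Tn + tokenIdx
  d <- nrow(x$val)
  tapeAdd(tp, x$val[, idx, drop = FALSE], list(x), function(g) {
    dx <- matrix(0, d, Tn * B)
    dx[, idx] <- g
    list(dx)
  })
}

## ---- optimizer and schedule ------------------------------------------------

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    if (is.null(g)) next
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    params[[i]] <- params[[i]] -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Cosine annealing learning-rate schedule
#'
#' Learning rate at a given epoch under cosine annealing from `lr0` down to
#' (essentially) zero over `epochs` epochs: the rate is `lr0` at epoch 0 and 0
#' at the final epoch.
#'
#' @param epoch zero-based epoch index.
#' @param epochs total number of epochs.
#' @param lr0 initial learning rate.
#' @return the learning rate, a single numeric.
#' @examples
#' cosineAnnealLr(0, 400)     # 0.001
#' cosineAnnealLr(399, 400)   # 0
#' @export
cosineAnnealLr <- function(epoch, epochs, lr0 = 0.001) {
  stopifnot(epochs >= 1L, epoch >= 0L, epoch < epochs)
  if (epochs == 1L) return(lr0)
  lr0 * 0.5 * (1 + cos(pi * epoch / (epochs - 1)))
}
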