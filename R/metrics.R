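## Evaluation statistics: Dice overlap, Bland-Altman agreement, ROC/AUC with
## the Youden operating point, stratified k-fold partitions, and the
## independent t-test used for model comparisons.

#' Dice similarity coefficient
#'
#' Spatial overlap `2|P n T| / (|P| + |T|)` between a predicted and a
#' reference mask for one class label. Defined as 1 when both masks are
#' empty.
#'
#' @param pred,truth aligned label matrices (or logical masks when
#'   `classLabel` is NULL).
#' @param classLabel the label value compared (default 1, the LA cavity).
#' @return DSC in [0, 1].
#' @examples
#' m <- matrix(c(1, 1, 0, 0), 2)
#' diceCoef(m, m)  # 1
#' @export
diceCoef <- function(pred, truth, classLabel = 1L) {
  if (!identical(dim(pred), dim(truth))) stop("mask shape mismatch")
  p <- if (is.null(classLabel)) as.logical(pred) else pred == classLabel
  t <- if (is.null(classLabel)) as.logical(truth) else truth == classLabel
  denom <- sum(p) + sum(t)
  if (denom == 0) return(1)
  2 * sum(p & t) / denom
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean difference), the standard deviation of the differences
#' (sample, n - 1), and the 95% limits of agreement `bias +/- 1.96 * sd`.
#'
#' @param x extracted (method) values.
#' @param y reference values, same length (>= 2).
#' @return a list with `bias`, `sdDiff`, `loaLow`, `loaHigh`, `n`.
#' @examples
#' blandAltman(c(1, 2, 3), c(1.1, 2.1, 3.1))$bias  # -0.1
#' @export
blandAltman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("at least 2 pairs are required")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sdDiff = s, loaLow = bias - 1.96 * s,
       loaHigh = bias + 1.96 * s, n = length(d))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney U probability that a random positive scores
#' above a random negative, with ties counted one half (mid-rank
#' formulation).
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1 or logical); both classes must be
#'   present.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  if (length(scores) != length(y)) stop("scores and labels must align")
  nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
  if (nPos == 0L || nNeg == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Youden-optimal operating point
#'
#' Sweeps candidate thresholds (midpoints of sorted unique scores, plus one
#' below the minimum and one above the maximum; predict positive when
#' `score >= threshold`) and returns the threshold maximizing Youden's
#' J = sensitivity + specificity - 1, with ties resolved to the lowest
#' threshold.
#'
#' @inheritParams rocAuc
#' @return a list with `threshold`, `sensitivity`, `specificity`,
#'   `accuracy`, `j`.
#' @export
youdenOperatingPoint <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
  if (nPos == 0L || nNeg == 0L) stop("both classes must be present")
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  best <- NULL
  for (thr in cand) {
    pred <- as.integer(scores >= thr)
    sens <- sum(pred == 1L & y == 1L) / nPos
    spec <- sum(pred == 0L & y == 0L) / nNeg
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(threshold = thr, sensitivity = sens, specificity = spec,
                   accuracy = mean(pred == y), j = j)
    }
  }
  best
}

#' Stratified k-fold partitions
#'
#' Partitions indices into k folds with per-fold class counts differing by
#' at most one from exact proportionality; shuffling is seeded.
#'
#' @param labels class labels (any type); each class must appear at least k
#'   times.
#' @param k number of folds (default 5).
#' @param seed integer seed for the shuffle.
#' @return a list of k elements, each a list with `train` and `test` index
#'   vectors.
#' @export
stratifiedKfold <- function(labels, k = 5L, seed = 1L) {
  k <- as.integer(k)
  tab <- table(labels)
  if (any(tab < k)) stop("every class must have at least k members")
  old <- .Random.seed_exists()
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  .restoreSeed(old)
  lapply(seq_len(k), function(f) {
    list(train = which(fold != f), test = which(fold == f))
  })
}

#' Independent two-sample t-test
#'
#' Two-sided independent t-test between two groups of per-image scores,
#' Welch (unequal variance) by default with a pooled-variance Student
#' option. Degenerate inputs with zero variance and equal means return
#' t = 0, p = 1.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @param varEqual use the pooled-variance Student test instead of Welch.
#' @return a list with `t` and `p`.
#' @export
independentTTest <- function(a, b, varEqual = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs at least 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = varEqual)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' ROC report at the Youden operating point
#'
#' Convenience bundle of [rocAuc()] and [youdenOperatingPoint()].
#'
#' @inheritParams rocAuc
#' @return list with `auc`, `threshold`, `sensitivity`, `specificity`,
#'   `accuracy`.
#' @export
rocReport <- function(scores, labels) {
  op <- youdenOperatingPoint(scores, labels)
  list(auc = rocAuc(scores, labels), threshold = op$threshold,
       sensitivity = op$sensitivity, specificity = op$specificity,
       accuracy = op$accuracy)
}
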