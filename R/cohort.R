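## Synthetic patient cohorts.
##
## Patients fall into three AHRE-duration groups (< 6 min, 6 min - 24 h,
## >= 24 h). Within each group the clinical features are drawn from published
## baseline marginals of a 117-patient CIED cohort: Gaussians (winsorized to
## plausible ranges) for the continuous features, Bernoulli prevalences for
## the binaries, and a per-group Gaussian for LA peak strain whose mean falls
## from 31.1% through 27.2% to 19.9% across the groups. Strains are fractions
## internally; percent appears only at I/O boundaries.

.grpNames <- c("ahre_lt_6min", "ahre_6min_24h", "ahre_ge_24h")

#' Cohort simulation specification
#'
#' Per-AHRE-group distribution settings for [simulateCohort()]. Defaults
#' reproduce the baseline-characteristics table of the reference cohort
#' (group sizes 64/40/13 of 117). Continuous entries are `c(mean, sd)` per
#' group; binary entries are per-group prevalences. The cohort table has no
#' BSA or separate MI/CAD rows, so BSA defaults to Normal(1.7, 0.2) m^2 and
#' MI/CAD prevalence is folded from the vascular-disease row (27/117
#' overall); both are overridable here.
#'
#' @param probs group membership probabilities (sum to 1).
#' @param age,bmi,chadsVasc,strainPct,burdenPct 2 x 3 matrices `rbind(mean,
#'   sd)` with one column per group; `strainPct` is LA peak strain in
#'   percent.
#' @param male,htn,dm,thyroid,vascular per-group prevalences.
#' @param bsa `c(mean, sd)` for body surface area, m^2.
#' @param durationRange 2 x 3 matrix of per-group AHRE-duration intervals in
#'   minutes (durations are drawn log-uniformly within the group interval).
#' @return a named list.
#' @export
cohortSpec <- function(probs = c(64, 40, 13) / 117,
                       age = rbind(c(74.8, 77.4, 76.2), c(11.2, 7.9, 10.0)),
                       bmi = rbind(c(24.6, 23.9, 24.3), c(4.1, 3.6, 4.2)),
                       chadsVasc = rbind(c(3.6, 3.9, 4.2), c(1.4, 1.2, 1.6)),
                       strainPct = rbind(c(31.1, 27.2, 19.9), c(11.0, 8.3, 9.0)),
                       burdenPct = rbind(c(0.06, 2.4, 26.7), c(0.05, 6.1, 26.6)),
                       male = c(30 / 64, 11 / 40, 6 / 13),
                       htn = c(46 / 64, 32 / 40, 11 / 13),
                       dm = c(20 / 64, 17 / 40, 6 / 13),
                       thyroid = c(6 / 64, 6 / 40, 6 / 13),
                       vascular = c(17 / 64, 8 / 40, 2 / 13),
                       bsa = c(1.7, 0.2),
                       durationRange = rbind(c(0.05, 6, 1440),
                                             c(6, 1440, 43200))) {
  if (abs(sum(probs) - 1) > 1e-8) stop("group probabilities must sum to 1")
  for (m in list(age, bmi, chadsVasc, strainPct, burdenPct))
    if (any(m[2, ] <= 0)) stop("all SDs must be positive")
  list(probs = probs, age = age, bmi = bmi, chadsVasc = chadsVasc,
       strainPct = strainPct, burdenPct = burdenPct, male = male, htn = htn,
       dm = dm, thyroid = thyroid, vascular = vascular, bsa = bsa,
       durationRange = durationRange)
}

.rnormClip <- function(n, mean, sd, lo, hi) pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)

#' Strain curve consistent with a given peak
#'
#' Builds a reservoir-shaped 30-point strain curve: zero at the base frame
#' (index 1), a raised-cosine rise to exactly `peak` at a mid-curve index,
#' then a fall towards a plateau, with additive Gaussian noise clipped so
#' the maximum stays `peak` and the base value stays 0.
#'
#' @param peak peak fractional strain (> -1).
#' @param T number of points (default 30, >= 2).
#' @param noiseSd additive Gaussian noise sd (fraction units).
#' @param seed optional integer seed.
#' @return numeric vector of length `T`.
#' @examples
#' max(strainCurveFromPeak(0.25, noiseSd = 0))  # 0.25
#' @export
strainCurveFromPeak <- function(peak, T = 30L, noiseSd = 0.01, seed = NULL) {
  T <- as.integer(T)
  if (T < 2L) stop("T must be at least 2")
  if (peak <= -1) stop("peak must exceed -1")
  if (!is.null(seed)) { old <- .Random.seed_exists(); set.seed(seed) }
  m <- max(2L, as.integer(round(0.4 * T)))
  t <- seq_len(T)
  plateau <- 0.45 * peak
  v <- numeric(T)
  up <- t <= m
  v[up] <- peak * 0.5 * (1 - cos(pi * (t[up] - 1) / (m - 1)))
  v[!up] <- plateau + (peak - plateau) * 0.5 * (1 + cos(pi * (t[!up] - m) / (T - m)))
  if (noiseSd > 0) v <- v + stats::rnorm(T, 0, noiseSd)
  v <- pmin(v, peak)
  v[1] <- 0
  v[m] <- peak
  if (!is.null(seed)) .restoreSeed(old)
  v
}

#' Simulate a synthetic patient cohort
#'
#' Draws `n` patients: multinomial AHRE-group membership, per-group clinical
#' feature marginals per the specification, a per-group LA peak strain
#' (converted from percent to fraction), a log-uniform AHRE duration within
#' the group's interval, and a full 30-point strain curve consistent with
#' each patient's peak strain.
#'
#' @param n number of patients (>= 0).
#' @param spec a [cohortSpec()].
#' @param seed integer seed; identical `(n, spec, seed)` give identical
#'   cohorts.
#' @param curveNoiseSd noise sd for the per-patient strain curves.
#' @return a data.frame with one row per patient: id, age, sex, bmi, bsa,
#'   chads_vasc, mi, cad, thyroid, dm, htn, ahre_minutes, ahre_burden_pct,
#'   peak_strain (fraction), ahre_group, strain_t00 ... strain_t29.
#' @export
simulateCohort <- function(n, spec = cohortSpec(), seed = 1L,
                           curveNoiseSd = 0.01) {
  if (n < 0) stop("n must be non-negative")
  n <- as.integer(n)
  cols <- c("id", "age", "sex", "bmi", "bsa", "chads_vasc", "mi", "cad",
            "thyroid", "dm", "htn", "ahre_minutes", "ahre_burden_pct",
            "peak_strain", "ahre_group", sprintf("strain_t%02d", 0:29))
  if (n == 0L) {
    out <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(out) <- cols
    return(out)
  }
  old <- .Random.seed_exists()
  set.seed(seed)
  g <- sample.int(3L, n, replace = TRUE, prob = spec$probs)
  draw <- function(m) stats::rnorm(n, m[1, g], m[2, g])
  age <- pmin(pmax(draw(spec$age), 40), 100)
  bmi <- pmin(pmax(draw(spec$bmi), 14), 45)
  bsa <- pmin(pmax(stats::rnorm(n, spec$bsa[1], spec$bsa[2]), 1.2), 2.5)
  chads <- pmin(pmax(round(draw(spec$chadsVasc)), 0), 9)
  strainPct <- pmin(pmax(draw(spec$strainPct), 0.5), 70)
  burden <- pmin(pmax(draw(spec$burdenPct), 0), 100)
  male <- stats::rbinom(n, 1L, spec$male[g])
  htn <- stats::rbinom(n, 1L, spec$htn[g])
  dm <- stats::rbinom(n, 1L, spec$dm[g])
  thyroid <- stats::rbinom(n, 1L, spec$thyroid[g])
  mi <- stats::rbinom(n, 1L, spec$vascular[g])
  cad <- stats::rbinom(n, 1L, spec$vascular[g])
  lo <- spec$durationRange[1, g]; hi <- spec$durationRange[2, g]
  ahre <- exp(stats::runif(n, log(lo), log(hi)))
  peak <- strainPct / 100
  curves <- t(vapply(seq_len(n), function(i)
    strainCurveFromPeak(peak[i], 30L, curveNoiseSd), numeric(30L)))
  .restoreSeed(old)
  out <- data.frame(
    id = sprintf("P%05d", seq_len(n)), age = age,
    sex = ifelse(male == 1L, "male", "female"), bmi = bmi, bsa = bsa,
    chads_vasc = as.integer(chads), mi = mi, cad = cad, thyroid = thyroid,
    dm = dm, htn = htn, ahre_minutes = ahre, ahre_burden_pct = burden,
    peak_strain = peak,
    ahre_group = factor(.grpNames[g], levels = .grpNames),
    stringsAsFactors = FALSE)
  colnames(curves) <- sprintf("strain_t%02d", 0:29)
  cbind(out, as.data.frame(curves))
}

#' Combine per-group means into an overall mean
#'
#' Patient-count-weighted average, the arithmetic that ties a summary
#' table's group columns to its overall column.
#'
#' @param means per-group means.
#' @param ns per-group patient counts.
#' @return the overall mean.
#' @examples
#' combineGroupMeans(c(53.2, 56.2, 56.8), c(64, 40, 13))  # 54.6...
#' @export
combineGroupMeans <- function(means, ns) sum(means * ns) / sum(ns)

#' Summarize a cohort as a baseline-characteristics table
#'
#' Per-group patient counts, mean +/- SD for the continuous features, and
#' count (%) for the binaries, plus an overall column formed as the
#' patient-count-weighted combination of the group columns (counts add,
#' means combine by weighted average).
#'
#' @param cohort a data.frame from [simulateCohort()].
#' @return a list with `n` (named counts), `continuous` (per-variable
#'   matrices of means/sds with an overall column), `binary` (counts and
#'   percents), and `table` (a formatted character data.frame).
#' @export
summarizeCohort <- function(cohort) {
  if (nrow(cohort) == 0L) stop("empty cohort")
  g <- cohort$ahre_group
  ns <- as.integer(table(g))
  names(ns) <- levels(g)
  contVars <- c(age = "age", bmi = "bmi", chads_vasc = "chads_vasc",
                bsa = "bsa", peak_strain_pct = "peak_strain",
                ahre_burden_pct = "ahre_burden_pct")
  continuous <- lapply(names(contVars), function(v) {
    x <- cohort[[contVars[[v]]]]
    if (v == "peak_strain_pct") x <- 100 * x
    mns <- tapply(x, g, mean)
    sds <- tapply(x, g, stats::sd)
    mns[is.na(mns)] <- NaN
    overall <- combineGroupMeans(mns[ns > 0], ns[ns > 0])
    rbind(mean = c(overall = overall, mns), sd = c(overall = stats::sd(x), sds))
  })
  names(continuous) <- names(contVars)
  binVars <- c(male = "sex", htn = "htn", dm = "dm", thyroid = "thyroid",
               mi = "mi", cad = "cad")
  binary <- lapply(names(binVars), function(v) {
    x <- if (v == "male") as.integer(cohort$sex == "male") else cohort[[binVars[[v]]]]
    cnt <- tapply(x, g, sum)
    cnt[is.na(cnt)] <- 0L
    cnt <- c(overall = sum(cnt), cnt)
    pct <- 100 * cnt / c(sum(ns), ns)
    rbind(count = cnt, pct = pct)
  })
  names(binary) <- names(binVars)
  fmt <- function(m) sprintf("%.1f ± %.1f", m[1, ], m[2, ])
  fmtB <- function(m) sprintf("%d (%.0f)", as.integer(m[1, ]), m[2, ])
  tab <- rbind(
    n = c(sum(ns), ns),
    do.call(rbind, c(lapply(continuous, fmt), lapply(binary, fmtB))))
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(tab) <- c("overall", levels(g))
  list(n = ns, continuous = continuous, binary = binary, table = tab)
}
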