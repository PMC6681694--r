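# Bland-Altman test-retest repeatability statistics on paired metric
# measurements. All distribution statistics operate on per-subject
# percent differences (%-delta), making them scale-free: multiplying
# every measurement by a positive constant changes nothing.

#' Paired test-retest measurements of one metric
#'
#' A plain `data.frame` container: one row per subject with the session-1
#' and session-2 values. Validates that subjects are unique and values
#' finite; a positive pair mean is required later, at %-delta time.
#'
#' @param subject character vector of subject IDs (unique).
#' @param m1,m2 numeric vectors, session-1 and session-2 measurements.
#' @param metric metric name (label carried in the `"metric"` attribute).
#' @return A `data.frame` with columns `subject`, `m1`, `m2`.
#' @export
pairedMeasurements <- function(subject, m1, m2, metric = "metric") {
  subject <- as.character(subject)
  if (anyDuplicated(subject))
    stop("each subject must appear exactly once")
  if (length(m1) != length(subject) || length(m2) != length(subject))
    stop("subject, m1 and m2 must have equal length")
  if (any(!is.finite(m1)) || any(!is.finite(m2)))
    stop("measurements must be finite")
  out <- data.frame(subject = subject, m1 = m1, m2 = m2,
                    stringsAsFactors = FALSE)
  attr(out, "metric") <- metric
  out
}

#' Percent difference between two paired measurements
#'
#' `%-delta = 100 * (m2 - m1) / ((m1 + m2) / 2)`: the relative
#' test-retest difference, normalized by the pair mean (the quantity a
#' Bland-Altman plot places on the x-axis), not by the first measurement.
#' Antisymmetric under swapping m1 and m2. Undefined (error) when the
#' pair mean is not positive.
#'
#' @param m1,m2 numeric vectors of paired measurements.
#' @return Percent differences, same length as the inputs.
#' @examples
#' percentDifference(9, 11)  # +20
#' @export
percentDifference <- function(m1, m2) {
  pm <- (m1 + m2) / 2
  if (any(pm <= 0))
    stop("pair mean must be positive for a percent difference")
  100 * (m2 - m1) / pm
}

#' Bland-Altman repeatability summary of one metric
#'
#' Computes per-subject percent differences and their distribution
#' statistics: mean, sample SD (n-1 denominator), within-subject
#' coefficient of variation `wCV = SD / divisor`, repeatability
#' coefficient `RC = 1.96 * SD`, limits of repeatability `mean +/- RC`
#' (within which about 95% of %-deltas are expected to fall), mean
#' |%-delta|, and a Shapiro-Wilk normality diagnostic of the %-delta
#' distribution (numeric surrogate for visual Q-Q inspection; NA when
#' n < 3).
#'
#' The divisor convention: with per-measurement within-subject
#' coefficient of variation `cv`, the SD of the %-delta of two
#' independent measurements is about `100 * cv * sqrt(2)`, so dividing by
#' `sqrt(2)` recovers the per-measurement wCV. `divisor = "2"` implements
#' the SD/2 convention instead. Both are reported side by side by
#' `as.data.frame`.
#'
#' @param pairs a [pairedMeasurements()] data frame (or any data frame
#'   with columns `m1`, `m2`).
#' @param wcvDivisor `"sqrt2"` (default) or `"2"`.
#' @return A [RepeatabilitySummary-class].
#' @examples
#' p <- pairedMeasurements(1:3, c(10, 10, 10), c(10 * 19 / 21, 10, 10 * 21 / 19))
#' repeatabilitySummary(p)  # mean 0, SD 10, RC 19.6
#' @export
repeatabilitySummary <- function(pairs, wcvDivisor = c("sqrt2", "2")) {
  wcvDivisor <- match.arg(wcvDivisor)
  n <- nrow(pairs)
  if (n < 2L)
    stop("need at least 2 paired subjects, got ", n)
  pd <- percentDifference(pairs$m1, pairs$m2)
  mu <- mean(pd)
  s <- stats::sd(pd)
  div <- if (wcvDivisor == "sqrt2") sqrt(2) else 2
  if (n >= 3L && n <= 5000L && s > 0) {
    sw <- stats::shapiro.test(pd)
    W <- unname(sw$statistic); p <- sw$p.value
  } else {
    W <- NA_real_; p <- NA_real_
  }
  new("RepeatabilitySummary",
      metric = as.character(attr(pairs, "metric") %||% "metric"),
      n = as.integer(n), meanPctDelta = mu, sdPctDelta = s,
      wcv = s / div, wcvDivisor = wcvDivisor, rc = 1.96 * s,
      lor = c(mu - 1.96 * s, mu + 1.96 * s), meanAbsPctDelta = mean(abs(pd)),
      normalityW = W, normalityP = p)
}

#' Fraction of subjects inside the repeatability-coefficient interval
#'
#' The %-delta of a pair is expected to fall within one repeatability
#' coefficient of the mean %-delta (either direction) in about 95% of
#' cases; this computes the empirical fraction
#' `|%-delta_i - mean| <= RC`.
#'
#' @param pairs a [pairedMeasurements()] data frame.
#' @param summary the [RepeatabilitySummary-class] for those pairs (or a
#'   reference population).
#' @return Fraction in `[0, 1]`.
#' @export
coverageCheck <- function(pairs, summary) {
  pd <- percentDifference(pairs$m1, pairs$m2)
  mean(abs(pd - summary@meanPctDelta) <= summary@rc)
}

#' Wilcoxon signed-rank test for paired data
#'
#' Two-sided; zero differences are dropped before ranking (Wilcoxon's
#' original convention -- consequential at small n). The p-value is exact
#' for up to 25 nonzero untied differences and a tie-corrected normal
#' approximation otherwise. When every difference is zero the test is
#' vacuous: p = 1 with `allZero = TRUE`.
#'
#' @param a,b numeric vectors of paired observations (equal length).
#' @return A list: `statistic` (V, sum of positive-difference ranks), `p`
#'   (two-sided), `nUsed` (nonzero differences), `allZero`, `exact`.
#' @export
wilcoxonSignedRank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  dnz <- d[d != 0]
  if (length(dnz) == 0L)
    return(list(statistic = 0, p = 1, nUsed = 0L, allZero = TRUE,
                exact = TRUE))
  n <- length(dnz)
  hasTies <- anyDuplicated(abs(dnz)) > 0L
  exact <- n <= 25L && !hasTies
  wt <- suppressWarnings(
    stats::wilcox.test(dnz, mu = 0, exact = exact, correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1  # fully tied data: no evidence either way
  list(statistic = unname(wt$statistic), p = p, nUsed = n,
       allZero = FALSE, exact = exact)
}

#' Mann-Whitney U test for two independent groups
#'
#' Two-sided; exact for small untied samples (both groups together
#' untied, min group size condition as in `stats::wilcox.test`),
#' tie-corrected normal approximation otherwise.
#'
#' @param groupA,groupB numeric vectors (nonempty).
#' @return A list: `statistic` (U for group A), `p` (two-sided), `exact`.
#' @export
mannWhitneyU <- function(groupA, groupB) {
  if (length(groupA) == 0L || length(groupB) == 0L)
    stop("both groups must be nonempty")
  hasTies <- anyDuplicated(c(groupA, groupB)) > 0L
  exact <- !hasTies && length(groupA) <= 25L && length(groupB) <= 25L
  wt <- suppressWarnings(
    stats::wilcox.test(groupA, groupB, exact = exact, correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1  # fully tied data: no evidence either way
  list(statistic = unname(wt$statistic), p = p, exact = exact)
}

#' Benjamini-Hochberg step-up procedure
#'
#' Sorts the m p-values ascending and rejects all hypotheses up to the
#' largest k with `p(k) <= k * q / m`, controlling the false-discovery
#' rate at q. Also reports the realized significance cutoff -- the
#' largest rejected raw p-value (these cutoffs are sample-dependent
#' outputs, not constants). Implemented via `stats::p.adjust(method =
#' "BH")`, whose adjusted values <= q reproduce the step-up rule exactly.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param q target false-discovery rate (default 0.05).
#' @return A list: `reject` (logical, input order), `adjusted` (BH
#'   adjusted p-values), `cutoff` (largest rejected raw p, or 0 when none
#'   rejected), `nRejected`, `q`.
#' @export
benjaminiHochberg <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stopifnot(q >= 0, q <= 1)
  adj <- stats::p.adjust(p, method = "BH")
  reject <- adj <= q
  list(reject = reject, adjusted = adj,
       cutoff = if (any(reject)) max(p[reject]) else 0,
       nRejected = sum(reject), q = q)
}

#' Shapiro-Wilk normality diagnostic
#'
#' A numeric stand-in for visual Q-Q plot inspection of a %-delta
#' distribution.
#'
#' @param x numeric vector, length >= 3 (and <= 5000), not all equal.
#' @return A list: `statistic` (W), `p`.
#' @export
normalityDiagnostic <- function(x) {
  if (length(x) < 3L)
    stop("normality diagnostic requires at least 3 values")
  sw <- stats::shapiro.test(x)
  list(statistic = unname(sw$statistic), p = sw$p.value)
}

#' Does a natural-log transform improve normality of paired differences?
#'
#' Recomputes the repeatability distribution on the log scale
#' (`100 * (log m2 - log m1)`, the log-scale analog of %-delta) and
#' compares Shapiro-Wilk statistics with the raw %-delta branch.
#' Following standard Bland-Altman practice for repeatability, the main
#' analysis proceeds on the untransformed %-deltas regardless; this is a
#' diagnostic report only.
#'
#' @param pairs a [pairedMeasurements()] data frame with positive
#'   measurements.
#' @return A list: `raw` and `log` (each `statistic`, `p`), `improved`
#'   (logical: log branch has the higher W).
#' @export
logTransformCheck <- function(pairs) {
  if (any(pairs$m1 <= 0) || any(pairs$m2 <= 0))
    stop("log transform requires positive measurements")
  pd <- percentDifference(pairs$m1, pairs$m2)
  ld <- 100 * (log(pairs$m2) - log(pairs$m1))
  raw <- normalityDiagnostic(pd)
  lg <- normalityDiagnostic(ld)
  list(raw = raw, log = lg, improved = lg$statistic > raw$statistic)
}
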