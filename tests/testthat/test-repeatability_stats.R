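test_that("percent difference normalizes by the pair mean and is antisymmetric", {
  expect_equal(percentDifference(10, 10), 0)
  expect_equal(percentDifference(9, 11), 20)
  set.seed(71)
  m1 <- runif(20, 1, 10); m2 <- runif(20, 1, 10)
  expect_equal(percentDifference(m1, m2), -percentDifference(m2, m1))
  expect_error(percentDifference(-3, 1), "positive")
})

test_that("repeatability summary reproduces the closed-form statistics", {
  # pairs engineered so the percent differences are exactly -10, 0, +10
  p <- pairedMeasurements(c("a", "b", "c"), c(10, 10, 10),
                          c(10 * 19 / 21, 10, 10 * 21 / 19),
                          metric = "suv_max")
  s <- repeatabilitySummary(p, "sqrt2")
  expect_equal(s@meanPctDelta, 0)
  expect_equal(s@sdPctDelta, 10)
  expect_equal(s@rc, 19.6)
  expect_equal(s@lor, c(-19.6, 19.6))
  expect_equal(s@wcv, 10 / sqrt(2))
  expect_equal(repeatabilitySummary(p, "2")@wcv, 5)
  expect_equal(s@meanAbsPctDelta, 20 / 3)

  ident <- pairedMeasurements(1:4, c(2, 3, 4, 5), c(2, 3, 4, 5))
  s0 <- repeatabilitySummary(ident)
  expect_equal(s0@meanPctDelta, 0)
  expect_equal(s0@sdPctDelta, 0)
  expect_equal(s0@rc, 0)
  expect_equal(s0@wcv, 0)
  expect_equal(s0@meanAbsPctDelta, 0)

  expect_error(repeatabilitySummary(pairedMeasurements("a", 1, 2)),
               "at least 2")
})

test_that("RC is exactly 1.96 SD and both wCV conventions are reported", {
  set.seed(73)
  for (i in 1:30) {
    n <- sample(3:40, 1)
    p <- pairedMeasurements(seq_len(n), runif(n, 1, 20), runif(n, 1, 20))
    s <- repeatabilitySummary(p)
    expect_identical(s@rc, 1.96 * s@sdPctDelta)
    expect_equal(diff(s@lor), 2 * s@rc)
    df <- as.data.frame(s)
    expect_equal(df$wcv_sqrt2, s@sdPctDelta / sqrt(2))
    expect_equal(df$wcv_2, s@sdPctDelta / 2)
    expect_gte(s@meanAbsPctDelta, abs(s@meanPctDelta))
  }
})

test_that("session relabeling negates the mean and scaling changes nothing", {
  set.seed(79)
  n <- 14
  m1 <- rlnorm(n, 2, 0.3); m2 <- m1 * exp(rnorm(n, 0, 0.1))
  a <- repeatabilitySummary(pairedMeasurements(1:n, m1, m2))
  b <- repeatabilitySummary(pairedMeasurements(1:n, m2, m1))
  expect_equal(b@meanPctDelta, -a@meanPctDelta)
  expect_equal(b@sdPctDelta, a@sdPctDelta)
  expect_equal(b@wcv, a@wcv)
  expect_equal(b@rc, a@rc)
  expect_equal(b@meanAbsPctDelta, a@meanAbsPctDelta)

  k <- 37.5
  sc <- repeatabilitySummary(pairedMeasurements(1:n, k * m1, k * m2))
  expect_equal(sc@meanPctDelta, a@meanPctDelta)
  expect_equal(sc@sdPctDelta, a@sdPctDelta)
  expect_equal(sc@meanAbsPctDelta, a@meanAbsPctDelta)
})

test_that("coverage check counts subjects within one RC of the mean", {
  p <- pairedMeasurements(c("a", "b", "c"), c(10, 10, 10),
                          c(10 * 19 / 21, 10, 10 * 21 / 19))
  s <- repeatabilitySummary(p)
  expect_equal(coverageCheck(p, s), 1.0)
  z <- pairedMeasurements(1:3, c(5, 6, 7), c(5, 6, 7))
  expect_equal(coverageCheck(z, repeatabilitySummary(z)), 1.0)
})

test_that("signed-rank test drops zeros, handles the all-zero case and small-n exacts", {
  a <- c(3, 5, 7, 9)
  res <- wilcoxonSignedRank(a, a)
  expect_equal(res$p, 1)
  expect_true(res$allZero)

  # five positive differences: one-tailed 1/32, two-sided 0.0625
  res5 <- wilcoxonSignedRank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(res5$p, 0.0625)
  expect_true(res5$exact)

  # zero differences are removed before ranking
  rz <- wilcoxonSignedRank(c(5, 2, 3, 4, 6, 7), c(5, 1, 1, 1, 1, 1))
  expect_identical(rz$nUsed, 5L)
  expect_equal(rz$p, 0.0625)
})

test_that("exact signed-rank p matches enumeration over all sign assignments", {
  set.seed(83)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    d <- round(runif(n, -5, 5), 3)
    d <- d[d != 0]
    if (length(d) < 2 || anyDuplicated(abs(d))) next
    res <- wilcoxonSignedRank(d, rep(0, length(d)))
    expect_true(res$exact)
    expect_equal(res$p, oracleSignedRankP(d))
  }
})

test_that("Mann-Whitney handles separation, identity and empty groups", {
  res <- mannWhitneyU(c(1, 2, 3), c(10, 20, 30))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.1)       # 2 / C(6,3) x 1 tail enumeration
  g <- c(4, 5, 6)
  resId <- mannWhitneyU(g, g)    # tied: approximate, maximal p
  expect_gte(resId$p, 0.99)
  expect_error(mannWhitneyU(numeric(0), g), "nonempty")
})

test_that("exact Mann-Whitney p matches enumeration over all labelings", {
  set.seed(89)
  for (i in 1:40) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    x <- round(runif(na + nb, 0, 100), 3)
    if (anyDuplicated(x)) next
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    res <- mannWhitneyU(a, b)
    expect_true(res$exact)
    expect_equal(res$p, oracleMannWhitneyP(a, b))
  }
})

test_that("BH step-up rejects per definition and reports the realized cutoff", {
  r <- benjaminiHochberg(c(0.001, 0.008, 0.039, 0.041), 0.05)
  expect_true(all(r$reject))            # p(4) = 0.041 <= 4*0.05/4
  expect_equal(r$cutoff, 0.041)

  expect_identical(benjaminiHochberg(rep(0.9, 6))$nRejected, 0L)
  expect_true(benjaminiHochberg(0.04, 0.05)$reject)
  expect_error(benjaminiHochberg(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("BH equals the literal step-up oracle and is monotone in q", {
  set.seed(97)
  for (i in 1:60) {
    m <- sample(2:20, 1)
    p <- round(runif(m)^sample(1:3, 1), 4)
    r <- benjaminiHochberg(p, 0.05)
    expect_identical(r$reject, oracleBH(p, 0.05))
    r2 <- benjaminiHochberg(p, 0.10)
    expect_true(all(r2$reject[r$reject]))   # larger q never un-rejects
  }
})

test_that("normality diagnostic separates near-ideal from outlier samples", {
  smooth <- normalityDiagnostic(seq(-2, 2, length.out = 14))
  expect_gt(smooth$p, 0.5)
  spike <- normalityDiagnostic(c(rep(0, 13), 50))
  expect_lt(spike$p, 0.001)
  expect_error(normalityDiagnostic(c(1, 2)), "at least 3")
})

test_that("log branch is more normal than raw for lognormal pairs most of the time", {
  set.seed(101)
  wins <- 0L
  reps <- 40L
  for (i in seq_len(reps)) {
    n <- 100
    M <- rlnorm(n, 1, 0.3)
    # heavy multiplicative error: the log differences are exactly normal
    # while the bounded %-delta (a tanh of them) is visibly platykurtic
    pairs <- pairedMeasurements(1:n, M * exp(rnorm(n, 0, 1)),
                                M * exp(rnorm(n, 0, 1)))
    if (logTransformCheck(pairs)$improved) wins <- wins + 1L
  }
  expect_gte(wins / reps, 0.9)
})

test_that("wCV converges to the generating within-subject CV", {
  set.seed(103)
  n <- 4000
  sw <- 0.10
  M <- rlnorm(n, 1.5, 0.4)
  pairs <- pairedMeasurements(seq_len(n), M * exp(rnorm(n, 0, sw)),
                              M * exp(rnorm(n, 0, sw)))
  sSqrt2 <- repeatabilitySummary(pairs, "sqrt2")
  s2 <- repeatabilitySummary(pairs, "2")
  expect_equal(sSqrt2@wcv, 100 * sw, tolerance = 0.03)
  expect_equal(s2@wcv, 100 * sw / sqrt(2), tolerance = 0.03)
})
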