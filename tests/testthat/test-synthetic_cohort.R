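test_that("metric cohort is deterministic under seed and exact at zero CV", {
  cfg0 <- cohortSimConfig(nSubjects = 10, withinSubjectCV = 0, seed = 5)
  pm0 <- simulateMetricCohort(cfg0)
  expect_equal(pm0$m1, pm0$m2)
  expect_equal(repeatabilitySummary(pm0)@wcv, 0)

  cfg <- cohortSimConfig(seed = 9)
  expect_identical(simulateMetricCohort(cfg), simulateMetricCohort(cfg))
  expect_identical(nrow(simulateMetricCohort(cfg)), 14L)
})

test_that("recovered wCV at n = 500 sits near the generating 10% CV", {
  cfg <- cohortSimConfig(nSubjects = 500, withinSubjectCV = 0.10,
                         seed = 107)
  s <- repeatabilitySummary(simulateMetricCohort(cfg), "sqrt2")
  expect_gt(s@wcv, 8.5)
  expect_lt(s@wcv, 11.5)
})

test_that("wCV estimates across replicate cohorts follow the 13-df chi spread", {
  # 200 cohorts of n = 14: the sample SD of %-deltas is (up to the tanh
  # compression of large relative differences) sigma * chi_13 / sqrt(13),
  # so the wCV estimate's quartiles follow the scaled chi quantiles
  set.seed(109)
  wcvs <- replicate(200, {
    cfg <- cohortSimConfig(nSubjects = 14, withinSubjectCV = 0.10)
    repeatabilitySummary(simulateMetricCohort(cfg), "sqrt2")@wcv
  })
  expect_lt(abs(median(wcvs) - 10), 1.5)
  chiQ <- function(p) 10 * sqrt(qchisq(p, df = 13) / 13)
  expect_equal(unname(quantile(wcvs, 0.25)), chiQ(0.25), tolerance = 0.06)
  expect_equal(unname(quantile(wcvs, 0.75)), chiQ(0.75), tolerance = 0.06)
})

test_that("noiseless unblurred phantom hits its ground truth exactly", {
  cfg <- phantomConfig(dims = c(20, 20, 16), spacing = c(2, 2, 3),
                       background = 1.2, amplitude = 6)
  f <- 1.07
  ph <- generateLesionPhantom(cfg, sessionFactor = f)
  expect_equal(metricExtremum(ph$volume, ph$mask, "max"), 1.2 + 6 * f)
  expect_equal(metricExtremum(ph$volume, ph$mask, "min"), 1.2 + 6 * f)
  expect_equal(ph$truth$lesionValue, 1.2 + 6 * f)
  expect_identical(voxelCount(ph$mask), as.integer(ph$truth$maskVoxels))
  # mask volume within a voxel-layer of the analytic ellipsoid volume
  expect_lt(abs(roiVolume(ph$mask) - ph$truth$ellipsoidVolumeML),
            4 * pi * 12^2 * 3 / 1000)
})

test_that("PSF blur conserves the uniform limit and noise obeys the seed", {
  cfg <- phantomConfig(dims = c(16, 16, 16), spacing = c(2, 2, 2),
                       background = 3, amplitude = 5, psfFwhmMm = 6,
                       noiseSd = 0, seed = 11)
  ph <- generateLesionPhantom(cfg, sessionFactor = 1)
  v <- imgValues(ph$volume)
  # blur moves counts out of the lesion but never above the true lesion
  # value or below background
  expect_lt(max(v), 8 + 1e-9)
  expect_gt(min(v), 3 - 1e-9)
  expect_lt(metricExtremum(ph$volume, ph$mask, "max"), 8)

  cfgN <- phantomConfig(dims = c(16, 16, 16), spacing = c(2, 2, 2),
                        amplitude = 5, noiseSd = 0.5, seed = 13)
  a <- generateLesionPhantom(cfgN, sessionFactor = 1)
  b <- generateLesionPhantom(cfgN, sessionFactor = 1)
  expect_identical(imgValues(a$volume), imgValues(b$volume))
})

test_that("session factors propagate to the exact %-delta of linear metrics", {
  cfg <- phantomConfig(dims = c(20, 20, 20), spacing = c(2, 2, 2),
                       background = 0, amplitude = 7, psfFwhmMm = 5)
  f <- c(0.93, 1.08)
  vols <- lapply(f, function(ff) generateLesionPhantom(cfg, ff))
  mget <- function(ph) metricValues(
    extractMetricSet(ph$volume, ph$mask, c("suv_mean", "suv_max")))
  m1 <- mget(vols[[1]]); m2 <- mget(vols[[2]])
  want <- 100 * (f[2] - f[1]) / mean(f)
  expect_equal(percentDifference(m1[["suv_mean"]], m2[["suv_mean"]]), want)
  expect_equal(percentDifference(m1[["suv_max"]], m2[["suv_max"]]), want)
})

test_that("phantom configs reject impossible lesions", {
  expect_error(phantomConfig(dims = c(10, 10, 10), spacing = c(1, 1, 1),
                             semiAxesMm = c(12, 10, 10)),
               "exceeds the grid")
  expect_error(phantomConfig(contrast = "cold", background = 1,
                             amplitude = 2), "amplitude < background")
})

test_that("a paired study writes volumes, masks, records and a stable manifest", {
  cc <- cohortSimConfig(nSubjects = 2, withinSubjectCV = 0.08, seed = 17)
  ph <- phantomConfig(dims = c(16, 16, 16), spacing = c(3, 3, 3),
                      semiAxesMm = c(12, 10, 10))
  d1 <- withr::local_tempdir()
  man <- generatePairedStudy(cc, ph, d1)
  # 2 subjects x 2 sessions x (PETCT PET + PETMR PET + PETMR ADC)
  expect_length(man$entries, 12)
  expect_identical(sort(names(man$ground_truth)), c("S01", "S02"))
  files <- list.files(d1)
  expect_identical(sum(grepl("_pet\\.nii\\.gz$", files)), 8L)
  expect_identical(sum(grepl("record\\.json$", files)), 8L)
  expect_true("manifest.json" %in% files)

  d2 <- withr::local_tempdir()
  generatePairedStudy(cc, ph, d2)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
})
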