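test_that("in-mask extremum, mean and median match direct computation", {
  u <- VolumeImage(array(7, c(4, 4, 4)), c(2, 2, 2), "SUV_g_per_mL")
  all4 <- RoiMask(array(TRUE, c(4, 4, 4)), c(2, 2, 2))
  expect_equal(metricExtremum(u, all4, "max"), 7)
  expect_equal(metricExtremum(u, all4, "min"), 7)
  expect_equal(unname(metricMeanMedian(u, all4)), c(7, 7))

  a <- array(0, c(4, 4, 4)); a[2, 3, 2] <- 10
  v <- VolumeImage(a, c(2, 2, 2), "SUV_g_per_mL")
  expect_equal(metricExtremum(v, all4, "max"), 10)
  expect_equal(metricExtremum(v, all4, "min"), 0)

  vals <- array(0, c(4, 4, 1))
  vals[1:4] <- c(1, 2, 3, 4)
  m <- array(FALSE, c(4, 4, 1)); m[1:4] <- TRUE
  mm <- metricMeanMedian(VolumeImage(vals, c(1, 1, 1), "SUV_g_per_mL"),
                         RoiMask(m, c(1, 1, 1)))
  expect_equal(unname(mm), c(2.5, 2.5))

  set.seed(7)
  for (i in 1:10) {
    rv <- randomMaskedVolume()
    inMask <- rv$vals[rv$maskArr]
    expect_equal(metricExtremum(rv$volume, rv$mask, "max"), max(inMask))
    expect_equal(metricExtremum(rv$volume, rv$mask, "min"), min(inMask))
    srt <- sort(inMask)
    n <- length(srt)
    med <- if (n %% 2) srt[(n + 1) / 2]
           else (srt[n / 2] + srt[n / 2 + 1]) / 2
    expect_equal(unname(metricMeanMedian(rv$volume, rv$mask)),
                 c(mean(inMask), med))
  }
})

test_that("sphere kernel approximates its target volume and scales with spacing", {
  k <- sphereKernel(c(2, 2, 2))
  expect_equal(k$radiusMm, (3000 / (4 * pi))^(1 / 3))
  expect_true(abs(k$realizedVolumeML - 1) < 0.25)
  kf <- sphereKernel(c(1, 1, 1))
  expect_true(abs(kf$realizedVolumeML - 1) < 0.05)
  # degenerate coarse spacing: a single-voxel kernel with an honestly
  # reported (poor) realized volume
  kc <- sphereKernel(c(20, 20, 20), 1)
  expect_identical(kc$nVoxels, 1L)
  expect_equal(kc$realizedVolumeML, 8)
})

test_that("sphere peak handles uniform, single-hot-voxel and symmetry cases", {
  u <- VolumeImage(array(3.5, c(12, 12, 12)), c(2, 2, 2), "SUV_g_per_mL")
  mk <- array(FALSE, c(12, 12, 12)); mk[5:8, 5:8, 5:8] <- TRUE
  mask <- RoiMask(mk, c(2, 2, 2))
  for (mode in c("max", "min"))
    expect_equal(metricPeakSphere(u, mask, mode = mode)$value, 3.5)

  a <- array(0, c(12, 12, 12)); a[6, 6, 6] <- 11
  v <- VolumeImage(a, c(2, 2, 2), "SUV_g_per_mL")
  pk <- metricPeakSphere(v, mask)
  K <- sphereKernel(c(2, 2, 2))$nVoxels
  expect_equal(pk$value, 11 / K)
  expect_false(pk$clipped)

  set.seed(13)
  rv <- randomMaskedVolume(dims = c(12, 12, 12), spacing = c(2, 2, 2))
  neg <- VolumeImage(-rv$vals, rv$spacing, "SUV_g_per_mL")
  expect_equal(metricPeakSphere(rv$volume, rv$mask, mode = "min")$value,
               -metricPeakSphere(neg, rv$mask, mode = "max")$value)
})

test_that("sphere peak equals the exhaustive center-scan oracle", {
  set.seed(29)
  for (i in 1:25) {
    dims <- sample(9:13, 3, replace = TRUE)
    sp <- runif(3, 2, 4)
    rv <- randomMaskedVolume(dims = dims, spacing = sp, pMask = 0.25)
    for (mode in c("max", "min")) {
      orc <- oraclePeakSphere(rv$vals, rv$maskArr, sp, mode = mode)
      got <- metricPeakSphere(rv$volume, rv$mask, mode = mode)
      if (is.null(orc)) {
        expect_true(got$clipped)
      } else {
        expect_false(got$clipped)
        expect_equal(got$value, orc)
      }
    }
  }
})

test_that("a kernel that fits nowhere falls back to a flagged clipped mean", {
  a <- array(1, c(4, 4, 4)); a[1, 1, 1] <- 9
  v <- VolumeImage(a, c(2, 2, 2), "SUV_g_per_mL")
  m <- array(FALSE, c(4, 4, 4)); m[1, 1, 1] <- TRUE
  pk <- metricPeakSphere(v, RoiMask(m, c(2, 2, 2)))
  expect_true(pk$clipped)
  expect_true(pk$value > 1 && pk$value <= 9)
})

test_that("percent isocontour keeps voxels at or above the max fraction", {
  u <- VolumeImage(array(4, c(5, 5, 5)), c(1, 1, 1), "SUV_g_per_mL")
  mk <- array(runif(125) < 0.5, c(5, 5, 5)); mk[3, 3, 3] <- TRUE
  mask <- RoiMask(mk, c(1, 1, 1))
  expect_identical(maskArray(percentIsocontour(u, mask, 0.4)), mk)

  vals <- array(0, c(3, 3, 1))
  vals[1:9] <- c(10, 5, 4, 3.9, 1, 0, 0, 0, 0)
  v <- VolumeImage(vals, c(1, 1, 1), "SUV_g_per_mL")
  m <- RoiMask(array(TRUE, c(3, 3, 1)), c(1, 1, 1))
  iso <- percentIsocontour(v, m, 0.4)
  expect_identical(voxelCount(iso), 3L)          # 10, 5 and 4 (threshold 4, inclusive)
  expect_true(all(vals[maskArray(iso)] >= 4))

  iso1 <- percentIsocontour(v, m, 1.0)
  expect_identical(which(maskArray(iso1)), which(vals == 10))

  zero <- VolumeImage(array(0, c(3, 3, 1)), c(1, 1, 1), "SUV_g_per_mL")
  expect_error(percentIsocontour(zero, m, 0.4), "non-positive")
})

test_that("isocontour is antitone in fraction and matches the oracle", {
  set.seed(37)
  for (i in 1:20) {
    rv <- randomMaskedVolume()
    f1 <- runif(1, 0.1, 0.5); f2 <- runif(1, 0.5, 1)
    isoLo <- maskArray(percentIsocontour(rv$volume, rv$mask, f1))
    isoHi <- maskArray(percentIsocontour(rv$volume, rv$mask, f2))
    expect_true(all(isoLo[isoHi]))               # higher fraction nested in lower
    expect_identical(isoLo, oracleIsocontour(rv$vals, rv$maskArr, f1))
    # argmax voxel always kept
    am <- rv$maskArr & (rv$vals == max(rv$vals[rv$maskArr]))
    expect_true(all(isoHi[am]))
  }
})

test_that("ROI volume is count x voxel volume, zero when empty, near analytic for ellipsoids", {
  mk <- array(FALSE, c(10, 10, 10)); mk[1:10, 1:10, 1:10][seq_len(1000)] <- TRUE
  expect_equal(roiVolume(RoiMask(mk, c(1, 1, 1))), 1.0)
  expect_equal(roiVolume(RoiMask(array(FALSE, c(4, 4, 4)), c(2, 2, 2))), 0)

  cfg <- phantomConfig(dims = c(30, 30, 30), spacing = c(1.5, 1.5, 1.5),
                       semiAxesMm = c(12, 10, 11))
  ph <- generateLesionPhantom(cfg, sessionFactor = 1)
  analytic <- 4 / 3 * pi * 12 * 10 * 11 / 1000
  # within one voxel-layer of the analytic volume: bound by the shell of
  # voxels straddling the surface
  surfaceShell <- 4 * pi * (11^2) * 1.5 / 1000   # area x one voxel edge
  expect_lt(abs(roiVolume(ph$mask) - analytic), surfaceShell)
})

test_that("total lesion glycolysis equals mean x volume and the direct sum", {
  u <- VolumeImage(array(2, c(10, 10, 10)), c(1, 1, 1), "SUV_g_per_mL")
  mk <- array(FALSE, c(10, 10, 10)); mk[seq_len(1000)] <- TRUE
  mask <- RoiMask(mk, c(1, 1, 1))
  expect_equal(totalLesionGlycolysis(u, mask), 2.0)

  set.seed(43)
  rv <- randomMaskedVolume()
  tlg <- totalLesionGlycolysis(rv$volume, rv$mask)
  vox <- prod(rv$spacing) / 1000
  expect_equal(tlg, sum(rv$vals[rv$maskArr]) * vox)
  expect_equal(tlg, mean(rv$vals[rv$maskArr]) * roiVolume(rv$mask))
  adc <- VolumeImage(rv$vals, rv$spacing, "ADC_1e-3_mm2_per_s")
  expect_error(totalLesionGlycolysis(adc, rv$mask), "SUV or SUL")
})

test_that("non-sphere metrics ignore mask-external voxels; sphere means may not", {
  set.seed(47)
  rv <- randomMaskedVolume(dims = c(12, 12, 12), spacing = c(2, 2, 2),
                           pMask = 0.15)
  vals2 <- rv$vals
  vals2[!rv$maskArr] <- vals2[!rv$maskArr] + 100
  v2 <- VolumeImage(vals2, rv$spacing, "SUV_g_per_mL")
  expect_equal(metricExtremum(v2, rv$mask, "max"),
               metricExtremum(rv$volume, rv$mask, "max"))
  expect_equal(metricMeanMedian(v2, rv$mask),
               metricMeanMedian(rv$volume, rv$mask))
  expect_equal(totalLesionGlycolysis(v2, rv$mask),
               totalLesionGlycolysis(rv$volume, rv$mask))
  # the sphere legitimately sees outside the contour
  expect_gt(metricPeakSphere(v2, rv$mask)$value,
            metricPeakSphere(rv$volume, rv$mask)$value)
})

test_that("extractMetricSet enforces kind compatibility and its orderings", {
  cfg <- phantomConfig(dims = c(20, 20, 20), spacing = c(2, 2, 2),
                       background = 1.8, amplitude = 0.9,
                       contrast = "cold", noiseSd = 0.05, seed = 3)
  ph <- generateLesionPhantom(cfg)
  ms <- extractMetricSet(ph$volume, ph$mask,
                         c("adc_median", "adc_trough",
                           "diffusional_tumor_volume_mL"))
  expect_setequal(names(metricValues(ms)),
                  c("adc_median", "adc_trough",
                    "diffusional_tumor_volume_mL"))

  suv <- VolumeImage(abs(imgValues(ph$volume)), c(2, 2, 2), "SUV_g_per_mL")
  expect_error(extractMetricSet(suv, ph$mask, "adc_trough"), "undefined")
  expect_error(extractMetricSet(suv, ph$mask, "bogus"), "unknown")

  set.seed(53)
  for (i in 1:5) {
    rv <- randomMaskedVolume(dims = c(14, 14, 14), spacing = c(2, 2, 2),
                             kind = "ADC_1e-3_mm2_per_s", pMask = 0.4)
    ms <- extractMetricSet(rv$volume, rv$mask)
    v <- metricValues(ms)
    expect_lte(v[["adc_min"]], v[["adc_trough"]])
    expect_lte(v[["adc_trough"]], v[["adc_mean"]])
    expect_lte(v[["adc_median"]], v[["adc_max"]])
    expect_gte(v[["adc_median"]], v[["adc_min"]])
    expect_gte(v[["diffusional_tumor_volume_mL"]], 0)
  }
})
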