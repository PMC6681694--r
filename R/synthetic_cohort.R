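# Synthetic ground-truth generators at two levels: metric-level paired
# cohorts (lognormal between-subject truth, multiplicative lognormal
# within-subject error) and image-level ellipsoid lesion phantoms
# (indicator lesion + Gaussian PSF blur + Gaussian noise). The defaults
# emulate the study design being modeled: 14 subjects, one pelvic lesion
# of >= 2.0 cm diameter each, two sessions, a 370-MBq dose, 15-min PET/CT
# and 30-min PET/MRI list-mode windows starting about 60 and 75 min
# post-injection.

#' Configuration for a metric-level paired cohort simulation
#'
#' True per-subject metric values are lognormal,
#' `M_i ~ exp(Normal(meanlog, sdlog))`; each session's measurement is
#' `m_ij = M_i * exp(eps_ij)` with `eps_ij ~ Normal(0, sigma_w^2)`
#' independent across subjects and sessions, where `sigma_w` is the
#' per-measurement within-subject coefficient of variation
#' (`withinSubjectCV`). Multiplicative error keeps percent-difference
#' statistics scale-free and distributionally clean.
#'
#' @param nSubjects number of subjects (default 14).
#' @param meanlog,sdlog between-subject lognormal parameters of the true
#'   metric (defaults `log(8)`, 0.4: an SUV_max-like scale).
#' @param withinSubjectCV per-measurement within-subject CV `sigma_w` as
#'   a fraction (default 0.10).
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return A list of class-free config fields, validated.
#' @export
cohortSimConfig <- function(nSubjects = 14L, meanlog = log(8),
                            sdlog = 0.4, withinSubjectCV = 0.10,
                            seed = NULL) {
  stopifnot(nSubjects >= 2, sdlog >= 0, withinSubjectCV >= 0)
  list(nSubjects = as.integer(nSubjects), meanlog = meanlog,
       sdlog = sdlog, withinSubjectCV = withinSubjectCV, seed = seed)
}

#' Simulate a paired test-retest cohort at the metric level
#'
#' @param config from [cohortSimConfig()].
#' @param metric metric label for the output.
#' @return A [pairedMeasurements()] data frame with a `"truth"` attribute
#'   (list: `M` true values, `eps` the n x 2 error matrix).
#' @export
simulateMetricCohort <- function(config, metric = "synthetic_metric") {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$nSubjects
  M <- stats::rlnorm(n, config$meanlog, config$sdlog)
  eps <- matrix(stats::rnorm(2 * n, 0, config$withinSubjectCV), n, 2)
  out <- pairedMeasurements(sprintf("S%02d", seq_len(n)),
                            M * exp(eps[, 1]), M * exp(eps[, 2]),
                            metric = metric)
  attr(out, "truth") <- list(M = M, eps = eps)
  out
}

#' Configuration for an ellipsoid lesion phantom
#'
#' The phantom is `background + amplitude * sessionFactor * indicator`
#' (contrast `"hot"`, PET-like) or `background - amplitude *
#' sessionFactor * indicator` (contrast `"cold"`, ADC-like: tumors are
#' dark on ADC maps), convolved with a Gaussian point-spread function of
#' the stated FWHM, plus white Gaussian noise. The mask is the pre-blur
#' ellipsoid indicator. All default values are arbitrary fixture choices,
#' except the lesion size floor: default semi-axes give a maximum
#' diameter of 2.4 cm, respecting a >= 2.0 cm inclusion criterion.
#'
#' @param dims grid shape (default `c(48, 48, 48)`).
#' @param spacing voxel spacing mm (default `c(2, 2, 2)`).
#' @param background background level in the volume's units.
#' @param amplitude lesion contrast amplitude (added for `"hot"`,
#'   subtracted for `"cold"`); must be positive, and the lesion must stay
#'   above background (hot) or above zero (cold).
#' @param semiAxesMm ellipsoid semi-axes (a, b, c) in mm (default
#'   `c(12, 10, 10)`).
#' @param center lesion center in voxel index coordinates (default: grid
#'   center).
#' @param psfFwhmMm Gaussian PSF full-width at half-maximum, mm (0 = no
#'   blur).
#' @param noiseSd additive Gaussian noise SD (0 = noiseless).
#' @param contrast `"hot"` or `"cold"`.
#' @param withinSubjectCV sigma_w used when session factors are drawn.
#' @param seed integer seed or NULL.
#' @return A validated config list.
#' @export
phantomConfig <- function(dims = c(48L, 48L, 48L), spacing = c(2, 2, 2),
                          background = 0, amplitude = 8,
                          semiAxesMm = c(12, 10, 10), center = NULL,
                          psfFwhmMm = 0, noiseSd = 0,
                          contrast = c("hot", "cold"),
                          withinSubjectCV = 0.10, seed = NULL) {
  contrast <- match.arg(contrast)
  stopifnot(length(dims) == 3L, all(dims >= 4), length(spacing) == 3L,
            all(spacing > 0), amplitude > 0, all(semiAxesMm > 0),
            psfFwhmMm >= 0, noiseSd >= 0, withinSubjectCV >= 0)
  if (is.null(center)) center <- (dims + 1) / 2
  # lesion must fit inside the grid
  extentVox <- semiAxesMm / spacing
  if (any(center - extentVox < 1) || any(center + extentVox > dims))
    stop("lesion ellipsoid exceeds the grid")
  if (contrast == "cold" && amplitude >= background)
    stop("cold lesion requires amplitude < background")
  list(dims = as.integer(dims), spacing = as.numeric(spacing),
       background = background, amplitude = amplitude,
       semiAxesMm = as.numeric(semiAxesMm), center = as.numeric(center),
       psfFwhmMm = psfFwhmMm, noiseSd = noiseSd, contrast = contrast,
       withinSubjectCV = withinSubjectCV, seed = seed)
}

# separable Gaussian convolution with boundary renormalization (a uniform
# volume stays exactly uniform)
.gaussianBlur3d <- function(a, fwhmMm, spacing) {
  if (fwhmMm <= 0) return(a)
  sigmaVox <- (fwhmMm / 2.354820045) / spacing
  w <- array(1, dim(a))
  for (d in 1:3) {
    s <- sigmaVox[d]
    if (s < 1e-6) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    kern <- stats::dnorm(-r:r, sd = s)
    kern <- kern / sum(kern)
    a <- .convolveAlong(a, kern, d)
    w <- .convolveAlong(w, kern, d)
  }
  a / w
}

# zero-padded 1D convolution of a 3D array along dimension d
.convolveAlong <- function(a, kern, d) {
  dims <- dim(a)
  perm <- c(d, setdiff(1:3, d))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = dims[d])
  n <- nrow(m)
  r <- (length(kern) - 1L) / 2L
  out <- matrix(0, n, ncol(m))
  for (i in seq_along(kern)) {
    sh <- i - r - 1L  # source row = target row + sh
    src <- seq_len(n) + sh
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + kern[i] * m[src[ok], ]
  }
  aperm(array(out, dims[perm]), order(perm))
}

.ellipsoidIndicator <- function(dims, spacing, center, semiAxesMm) {
  x <- ((seq_len(dims[1]) - center[1]) * spacing[1] / semiAxesMm[1])^2
  y <- ((seq_len(dims[2]) - center[2]) * spacing[2] / semiAxesMm[2])^2
  z <- ((seq_len(dims[3]) - center[3]) * spacing[3] / semiAxesMm[3])^2
  array(outer(outer(x, y, "+"), z, "+") <= 1, dims)
}

#' Generate one lesion phantom volume + mask with ground truth
#'
#' @param config from [phantomConfig()].
#' @param sessionFactor multiplicative within-subject session effect; if
#'   NULL, drawn as `exp(Normal(0, withinSubjectCV^2))`.
#' @param valueKind the value kind stamped on the volume (default
#'   `"SUV_g_per_mL"` for hot, `"ADC_1e-3_mm2_per_s"` for cold).
#' @return A list: `volume` ([VolumeImage-class]), `mask`
#'   ([RoiMask-class], the pre-blur indicator), `truth` (list:
#'   `lesionValue` = un-blurred in-lesion value, `sessionFactor`,
#'   `ellipsoidVolumeML` = analytic 4/3 pi a b c / 1000, `maskVoxels`).
#' @export
generateLesionPhantom <- function(config, sessionFactor = NULL,
                                  valueKind = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(sessionFactor))
    sessionFactor <- exp(stats::rnorm(1, 0, config$withinSubjectCV))
  if (is.null(valueKind))
    valueKind <- if (config$contrast == "hot") "SUV_g_per_mL"
                 else "ADC_1e-3_mm2_per_s"
  ind <- .ellipsoidIndicator(config$dims, config$spacing, config$center,
                             config$semiAxesMm)
  sgn <- if (config$contrast == "hot") 1 else -1
  lesionValue <- config$background + sgn * config$amplitude * sessionFactor
  if (lesionValue < 0)
    stop("session factor drives the cold lesion below zero")
  vals <- config$background + sgn * config$amplitude * sessionFactor * ind
  vals <- .gaussianBlur3d(vals, config$psfFwhmMm, config$spacing)
  if (config$noiseSd > 0)
    vals <- vals + array(stats::rnorm(length(vals), 0, config$noiseSd),
                         config$dims)
  list(volume = VolumeImage(vals, config$spacing, valueKind),
       mask = RoiMask(ind, config$spacing),
       truth = list(lesionValue = lesionValue,
                    sessionFactor = sessionFactor,
                    ellipsoidVolumeML = 4 / 3 * pi *
                      prod(config$semiAxesMm) / 1000,
                    maskVoxels = sum(ind)))
}

#' Generate an on-disk paired test-retest imaging study with ground truth
#'
#' Writes, per subject x session x modality, a NIfTI activity volume (PET
#' modalities) and/or an ADC map, the shared lesion mask, and a subject
#' JSON record, plus a `manifest.json` tying them together with the full
#' ground truth (true SUV amplitudes, session factors, acquisition
#' windows, seeds). PET activity concentrations are constructed so that
#' SUV conversion at the matched-frame start recovers
#' `trueSUV * sessionFactor` exactly; ADC phantoms use a cold lesion.
#'
#' Acquisition windows follow the emulated protocol: PET/CT 15 min
#' starting 60 min post-injection, PET/MRI 30 min starting at PET/CT end,
#' with a small per-session start jitter; frames are matched with the
#' latest-overlap policy for PET/CT and earliest for PET/MRI.
#'
#' @param cohortConfig from [cohortSimConfig()]; supplies n, the
#'   between-subject lognormal and sigma_w.
#' @param phantom from [phantomConfig()]; grid, PSF, noise and lesion
#'   geometry (its `amplitude`/`contrast`/`seed` are overridden per
#'   subject).
#' @param outDir output directory (created if needed).
#' @param modalities subset of `c("PETCT", "PETMR")`.
#' @param adc also write ADC maps for PETMR sessions (default TRUE when
#'   PETMR is included).
#' @param frameDurationMin static frame duration for the manifest windows
#'   (default 5).
#' @param adcMeanlog,adcSdlog,adcBackground between-subject lognormal of
#'   true lesion ADC and the ADC background, in 1e-3 mm^2/s.
#' @return The manifest, invisibly (also written to
#'   `file.path(outDir, "manifest.json")`).
#' @export
generatePairedStudy <- function(cohortConfig, phantom, outDir,
                                modalities = c("PETCT", "PETMR"),
                                adc = "PETMR" %in% modalities,
                                frameDurationMin = 5,
                                adcMeanlog = log(1.1), adcSdlog = 0.15,
                                adcBackground = 1.8) {
  modalities <- match.arg(modalities, several.ok = TRUE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cohortConfig$seed)) set.seed(cohortConfig$seed)
  n <- cohortConfig$nSubjects
  sw <- cohortConfig$withinSubjectCV

  ids <- sprintf("S%02d", seq_len(n))
  sexes <- c("male", rep("female", n - 1L))  # mostly-female pelvic cohort
  weights <- round(stats::runif(n, 60, 105), 1)
  heights <- round(stats::runif(n, 155, 185), 1)
  trueSUV <- stats::rlnorm(n, cohortConfig$meanlog, cohortConfig$sdlog)
  trueADC <- stats::rlnorm(n, adcMeanlog, adcSdlog)
  ctStart <- round(60 + stats::runif(n * 2, 0, 5), 1)  # per subject x session

  entries <- list()
  truthSubjects <- list()
  for (i in seq_len(n)) {
    starts <- ctStart[c(i, n + i)]
    wins <- list(
      PETCT = lapply(starts, acquisitionWindow, durationMin = 15),
      PETMR = lapply(starts + 15, acquisitionWindow, durationMin = 30))
    ivs <- list(
      PETCT = matchedInterval(wins$PETCT[[1]], wins$PETCT[[2]],
                              frameDurationMin, "latest"),
      PETMR = matchedInterval(wins$PETMR[[1]], wins$PETMR[[2]],
                              frameDurationMin, "earliest"))
    factors <- list()
    for (mod in modalities)
      factors[[mod]] <- exp(stats::rnorm(2, 0, sw))
    adcFactors <- if (adc) exp(stats::rnorm(2, 0, sw)) else NULL

    for (s in 1:2) {
      for (mod in modalities) {
        rec <- SubjectRecord(ids[i], sexes[i], weights[i], heights[i],
                             370, 0, session = s, modality = mod)
        recPath <- sprintf("%s_%s_s%d_record.json", ids[i], mod, s)
        writeSubjectRecord(rec, file.path(outDir, recPath))
        refT <- ivs[[mod]]$uptakeInterval[1]
        doseBq <- 1e6 * decayCorrectDose(370, 0, refT)
        concPerSUV <- doseBq / (1000 * weights[i])  # Bq/mL per SUV unit
        cfg <- phantom
        cfg$contrast <- "hot"
        cfg$background <- phantom$background * concPerSUV
        cfg$amplitude <- trueSUV[i] * concPerSUV
        cfg$noiseSd <- phantom$noiseSd * concPerSUV
        cfg$seed <- NULL
        ph <- generateLesionPhantom(cfg,
                                    sessionFactor = factors[[mod]][s],
                                    valueKind = "activity_Bq_per_mL")
        volPath <- sprintf("%s_%s_s%d_pet.nii.gz", ids[i], mod, s)
        maskPath <- sprintf("%s_%s_s%d_mask.nii.gz", ids[i], mod, s)
        writeVolume(ph$volume, file.path(outDir, volPath))
        writeVolume(ph$mask, file.path(outDir, maskPath))
        entries[[length(entries) + 1L]] <- list(
          subject_id = ids[i], session = s, modality = mod,
          value_kind = "activity_Bq_per_mL", volume = volPath,
          mask = maskPath, subject_record = recPath,
          window = list(start_min = wins[[mod]][[s]]$startMin,
                        duration_min = wins[[mod]][[s]]$durationMin))
      }
      if (adc) {
        cfgA <- phantom
        cfgA$contrast <- "cold"
        cfgA$background <- adcBackground
        cfgA$amplitude <- adcBackground - trueADC[i]
        cfgA$noiseSd <- phantom$noiseSd * 0.01
        cfgA$seed <- NULL
        if (cfgA$amplitude <= 0)
          cfgA$amplitude <- 0.1 * adcBackground  # degenerate draw guard
        phA <- generateLesionPhantom(cfgA,
                                     sessionFactor = adcFactors[s],
                                     valueKind = "ADC_1e-3_mm2_per_s")
        volPath <- sprintf("%s_PETMR_s%d_adc.nii.gz", ids[i], s)
        maskPath <- sprintf("%s_PETMR_s%d_adcmask.nii.gz", ids[i], s)
        writeVolume(phA$volume, file.path(outDir, volPath))
        writeVolume(phA$mask, file.path(outDir, maskPath))
        entries[[length(entries) + 1L]] <- list(
          subject_id = ids[i], session = s, modality = "PETMR",
          value_kind = "ADC_1e-3_mm2_per_s", volume = volPath,
          mask = maskPath,
          subject_record = sprintf("%s_PETMR_s%d_record.json", ids[i], s),
          window = list(start_min = starts[s] + 15, duration_min = 30))
      }
    }
    truthSubjects[[ids[i]]] <- list(
      true_suv = trueSUV[i], true_adc = trueADC[i],
      session_factors = factors, adc_factors = adcFactors,
      uptake_intervals = lapply(ivs, function(v) v$uptakeInterval))
  }
  manifest <- list(
    seed = cohortConfig$seed, n_subjects = n, within_subject_cv = sw,
    frame_duration_min = frameDurationMin, modalities = modalities,
    entries = entries, ground_truth = truthSubjects)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
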