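# SUV/SUL conversion. SUV normalizes tissue activity concentration by
# injected dose per body weight; SUL replaces body weight with the James
# (1976) lean body mass. The decay reference time is the start of the
# selected reconstruction frame.

#' Physical decay of F-18 half-life, minutes
#' @keywords internal
.F18_HALF_LIFE_MIN <- 109.771

#' Decay-correct an injected dose to a reference time
#'
#' Returns `dose * 2^(-(reference - injection) / halfLife)`. Correcting
#' over concatenated intervals is multiplicative, so correcting by dt1
#' then dt2 equals correcting by dt1 + dt2.
#'
#' @param doseMBq injected activity in MBq (> 0).
#' @param injectionTimeMin injection time, minutes.
#' @param referenceTimeMin decay reference time, minutes; must be >=
#'   `injectionTimeMin`.
#' @param halfLifeMin isotope half-life in minutes (default F-18,
#'   109.771 min).
#' @return Decayed activity in MBq.
#' @examples
#' decayCorrectDose(370, 0, 109.771)  # one half-life: 185
#' @export
decayCorrectDose <- function(doseMBq, injectionTimeMin, referenceTimeMin,
                             halfLifeMin = .F18_HALF_LIFE_MIN) {
  stopifnot(halfLifeMin > 0)
  dt <- referenceTimeMin - injectionTimeMin
  if (any(dt < 0))
    stop("reference time precedes injection time (dt = ",
         paste(signif(dt[dt < 0], 4), collapse = ", "), " min)")
  doseMBq * 2^(-dt / halfLifeMin)
}

#' Lean body mass by the James formula
#'
#' James (1976): males `1.10 W - 128 (W/H)^2`, females
#' `1.07 W - 148 (W/H)^2`, with W in kg and H in cm. For physiologic
#' inputs the result is below total body weight; for extreme obesity the
#' quadratic term can drive it to zero or below, which is treated as
#' out-of-domain and raised as an error.
#'
#' @param weightKg body weight, kg (> 0).
#' @param heightCm height, cm (> 0).
#' @param sex `"male"` or `"female"`.
#' @return Lean body mass in kg.
#' @examples
#' leanBodyMassJames(80, 180, "male")  # ~62.72
#' @export
leanBodyMassJames <- function(weightKg, heightCm, sex) {
  if (any(weightKg <= 0)) stop("weight must be positive")
  if (any(heightCm <= 0)) stop("height must be positive")
  sex <- match.arg(sex, c("male", "female"))
  r2 <- (weightKg / heightCm)^2
  lbm <- if (sex == "male") 1.10 * weightKg - 128 * r2
         else 1.07 * weightKg - 148 * r2
  if (any(lbm <= 0))
    stop("James formula yields non-positive lean body mass ",
         "(out-of-domain input)")
  lbm
}

#' Convert an activity-concentration volume to SUV
#'
#' Voxelwise `SUV = concentration [Bq/mL] / (decayed dose [Bq] /
#' weight [g])`, with the dose decay-corrected from injection time to
#' `referenceTimeMin` (by convention, the start of the reconstruction
#' frame). The conversion is a single positive scale factor, so the argmax
#' voxel location is preserved.
#'
#' @param volume a [VolumeImage-class] with value kind
#'   `activity_Bq_per_mL`.
#' @param subject the session's [SubjectRecord-class].
#' @param referenceTimeMin decay reference time, minutes post-injection
#'   origin; defaults to the volume's frame start when recorded.
#' @param halfLifeMin isotope half-life, minutes.
#' @return A [VolumeImage-class] with value kind `SUV_g_per_mL`.
#' @export
activityToSUV <- function(volume, subject, referenceTimeMin = NULL,
                          halfLifeMin = .F18_HALF_LIFE_MIN) {
  if (valueKind(volume) != "activity_Bq_per_mL")
    stop("expected value kind 'activity_Bq_per_mL', got '",
         valueKind(volume), "'")
  if (is.null(referenceTimeMin)) {
    if (length(volume@frameWindow) != 2L)
      stop("referenceTimeMin not given and volume has no frame window")
    referenceTimeMin <- volume@frameWindow[1]
  }
  doseBq <- 1e6 * decayCorrectDose(subject@injectedDoseMBq,
                                   subject@injectionTimeMin,
                                   referenceTimeMin, halfLifeMin)
  weightG <- 1000 * subject@weightKg
  VolumeImage(volume@values / (doseBq / weightG), volume@spacing,
              "SUV_g_per_mL", frameWindow = volume@frameWindow)
}

#' Convert an SUV volume to SUL
#'
#' Voxelwise `SUL = SUV * LBM / weight`, with LBM from
#' [leanBodyMassJames()]. Since LBM <= weight for physiologic inputs, SUL
#' <= SUV voxelwise. Composing [activityToSUV()] with `suvToSUL` is
#' algebraically identical to normalizing activity by dose per lean body
#' mass directly.
#'
#' @param volume a [VolumeImage-class] with value kind `SUV_g_per_mL`.
#' @param subject the session's [SubjectRecord-class].
#' @return A [VolumeImage-class] with value kind `SUL_g_per_mL`.
#' @export
suvToSUL <- function(volume, subject) {
  if (valueKind(volume) != "SUV_g_per_mL")
    stop("expected value kind 'SUV_g_per_mL', got '", valueKind(volume),
         "'")
  lbm <- leanBodyMassJames(subject@weightKg, subject@heightCm,
                           subject@sex)
  VolumeImage(volume@values * (lbm / subject@weightKg), volume@spacing,
              "SUL_g_per_mL", frameWindow = volume@frameWindow)
}
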