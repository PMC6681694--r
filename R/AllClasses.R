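#' @import methods
NULL

.VALUE_KINDS <- c("activity_Bq_per_mL", "SUV_g_per_mL", "SUL_g_per_mL",
                  "ADC_1e-3_mm2_per_s")

#' VolumeImage: a 3D scalar image with voxel spacing and a value kind
#'
#' The central image container. Holds a 3D numeric array in native NIfTI
#' index order (x, y, z), the voxel spacing `(dx, dy, dz)` in mm, and a
#' declared `valueKind` identifying the physical quantity stored:
#' `activity_Bq_per_mL` (PET activity concentration), `SUV_g_per_mL`,
#' `SUL_g_per_mL` (lean-body-mass-adjusted SUV) or `ADC_1e-3_mm2_per_s`
#' (apparent diffusion coefficient in 10^-3 mm^2/s). An optional
#' `frameWindow` records the reconstruction interval in minutes
#' post-injection.
#'
#' Validity requires a finite 3D array and strictly positive spacing, so
#' the voxel volume `dx*dy*dz/1000` mL is always derivable and positive.
#'
#' @slot values 3D numeric array, all finite.
#' @slot spacing numeric(3), voxel edge lengths (dx, dy, dz) in mm, all > 0.
#' @slot valueKind character(1), one of the four kinds above.
#' @slot frameWindow numeric(0) or numeric(2), (start, end) minutes
#'   post-injection of the reconstruction frame.
#' @seealso [VolumeImage()], [readVolume()], [voxelVolume()]
#' @exportClass VolumeImage
setClass("VolumeImage",
  representation(values = "array", spacing = "numeric",
                 valueKind = "character", frameWindow = "numeric"),
  prototype(frameWindow = numeric(0)))

setValidity("VolumeImage", function(object) {
  msgs <- character(0)
  if (length(dim(object@values)) != 3L)
    msgs <- c(msgs, sprintf("values must be a 3D array, got %d dimension(s)",
                            length(dim(object@values))))
  nbad <- sum(!is.finite(object@values))
  if (nbad > 0L)
    msgs <- c(msgs, sprintf("values contain %d non-finite voxel(s)", nbad))
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be three strictly positive numbers (mm)")
  if (length(object@valueKind) != 1L || !object@valueKind %in% .VALUE_KINDS)
    msgs <- c(msgs, paste0("valueKind must be one of: ",
                           paste(.VALUE_KINDS, collapse = ", ")))
  if (!length(object@frameWindow) %in% c(0L, 2L))
    msgs <- c(msgs, "frameWindow must be empty or (start, end)")
  if (length(object@frameWindow) == 2L &&
      diff(object@frameWindow) <= 0)
    msgs <- c(msgs, "frameWindow end must exceed start")
  if (length(msgs)) msgs else TRUE
})

#' Construct a VolumeImage
#'
#' @param values 3D numeric array of voxel values.
#' @param spacing numeric(3), voxel spacing (dx, dy, dz) in mm.
#' @param valueKind one of `"activity_Bq_per_mL"`, `"SUV_g_per_mL"`,
#'   `"SUL_g_per_mL"`, `"ADC_1e-3_mm2_per_s"`.
#' @param frameWindow optional numeric(2), frame (start, end) in minutes
#'   post-injection.
#' @return A [VolumeImage-class] object.
#' @examples
#' v <- VolumeImage(array(1, c(4, 4, 4)), spacing = c(2, 2, 2),
#'                  valueKind = "SUV_g_per_mL")
#' voxelVolume(v)  # 0.008 mL
#' @export
VolumeImage <- function(values, spacing, valueKind,
                        frameWindow = numeric(0)) {
  new("VolumeImage", values = values, spacing = as.numeric(spacing),
      valueKind = valueKind, frameWindow = as.numeric(frameWindow))
}

#' RoiMask: a binary 3D region-of-interest mask
#'
#' A voxelized tumor contour sharing the grid of a [VolumeImage-class]
#' (same array shape and spacing). Manual delineations are represented as
#' voxel masks; there is no mesh/contour geometry.
#'
#' @slot mask 3D logical array.
#' @slot spacing numeric(3), voxel spacing (dx, dy, dz) in mm, all > 0.
#' @seealso [RoiMask()], [readMask()], [roiVolume()]
#' @exportClass RoiMask
setClass("RoiMask",
  representation(mask = "array", spacing = "numeric"))

setValidity("RoiMask", function(object) {
  msgs <- character(0)
  if (length(dim(object@mask)) != 3L)
    msgs <- c(msgs, "mask must be a 3D array")
  if (!is.logical(object@mask))
    msgs <- c(msgs, "mask must be logical")
  if (anyNA(object@mask))
    msgs <- c(msgs, "mask must not contain NA")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be three strictly positive numbers (mm)")
  if (length(msgs)) msgs else TRUE
})

#' Construct an RoiMask
#'
#' @param mask 3D logical (or coercible 0/1 numeric) array; nonzero means
#'   inside the region.
#' @param spacing numeric(3), voxel spacing (dx, dy, dz) in mm.
#' @return An [RoiMask-class] object.
#' @export
RoiMask <- function(mask, spacing) {
  if (!is.logical(mask)) {
    dm <- dim(mask)
    mask <- array(as.logical(mask != 0), dm)
  }
  new("RoiMask", mask = mask, spacing = as.numeric(spacing))
}

#' SubjectRecord: demographics, dose and timing for one imaging session
#'
#' Per-(subject, session, modality) metadata needed for SUV/SUL conversion
#' (weight, height, sex, injected dose) and uptake-time bookkeeping
#' (injection time; acquisition timing lives in the study manifest). Times
#' are minutes post-injection, with the injection at 0 by convention.
#'
#' @slot subjectId character(1).
#' @slot sex `"male"` or `"female"` (the James lean-body-mass formula is
#'   sex-specific).
#' @slot weightKg numeric(1) > 0.
#' @slot heightCm numeric(1) > 0.
#' @slot injectedDoseMBq numeric(1) > 0.
#' @slot injectionTimeMin numeric(1), timestamp origin (0 by convention).
#' @slot session integer(1), 1 or 2.
#' @slot modality `"PETCT"` or `"PETMR"`.
#' @seealso [SubjectRecord()], [readSubjectRecord()]
#' @exportClass SubjectRecord
setClass("SubjectRecord",
  representation(subjectId = "character", sex = "character",
                 weightKg = "numeric", heightCm = "numeric",
                 injectedDoseMBq = "numeric", injectionTimeMin = "numeric",
                 session = "integer", modality = "character"))

setValidity("SubjectRecord", function(object) {
  msgs <- character(0)
  if (length(object@subjectId) != 1L || !nzchar(object@subjectId))
    msgs <- c(msgs, "subjectId must be a nonempty string")
  if (length(object@sex) != 1L || !object@sex %in% c("male", "female"))
    msgs <- c(msgs, "sex must be 'male' or 'female'")
  for (fld in c("weightKg", "heightCm", "injectedDoseMBq")) {
    v <- slot(object, fld)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msgs <- c(msgs, sprintf("%s must be a single positive number", fld))
  }
  if (length(object@session) != 1L || !object@session %in% c(1L, 2L))
    msgs <- c(msgs, "session must be 1 or 2")
  if (length(object@modality) != 1L ||
      !object@modality %in% c("PETCT", "PETMR"))
    msgs <- c(msgs, "modality must be 'PETCT' or 'PETMR'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SubjectRecord
#'
#' @param subjectId subject identifier.
#' @param sex `"male"` or `"female"`.
#' @param weightKg body weight in kg (> 0).
#' @param heightCm height in cm (> 0).
#' @param injectedDoseMBq injected tracer activity in MBq (> 0).
#' @param injectionTimeMin injection time in minutes (origin; default 0).
#' @param session imaging session, 1 or 2.
#' @param modality `"PETCT"` or `"PETMR"`.
#' @return A [SubjectRecord-class] object.
#' @export
SubjectRecord <- function(subjectId, sex, weightKg, heightCm,
                          injectedDoseMBq, injectionTimeMin = 0,
                          session = 1L, modality = "PETCT") {
  new("SubjectRecord", subjectId = as.character(subjectId), sex = sex,
      weightKg = as.numeric(weightKg), heightCm = as.numeric(heightCm),
      injectedDoseMBq = as.numeric(injectedDoseMBq),
      injectionTimeMin = as.numeric(injectionTimeMin),
      session = as.integer(session), modality = modality)
}

#' MetricSet: named scalar metrics extracted from one volume + mask
#'
#' The result of [extractMetricSet()]: a named numeric vector of metric
#' values keyed by metric name (`suv_max`, `sul_peak`, `adc_median`, ...),
#' the value kind of the source volume, and a `details` list carrying peak
#' sphere metadata (winning center, realized kernel volume, clipped-kernel
#' flag).
#'
#' @slot values named numeric vector of metric values.
#' @slot valueKind character(1), the source volume's value kind.
#' @slot details list of per-metric metadata.
#' @exportClass MetricSet
setClass("MetricSet",
  representation(values = "numeric", valueKind = "character",
                 details = "list"),
  prototype(details = list()))

setValidity("MetricSet", function(object) {
  if (length(object@values) && is.null(names(object@values)))
    return("values must be named")
  TRUE
})

#' RepeatabilitySummary: Bland-Altman statistics of one metric's %-deltas
#'
#' Holds the distribution statistics of per-subject percent differences
#' (%-delta) between two sessions for one metric: mean, sample SD,
#' within-subject coefficient of variation (wCV = SD / divisor), the
#' repeatability coefficient RC = 1.96 * SD, limits of repeatability
#' mean +/- RC, mean |%-delta|, and a Shapiro-Wilk normality diagnostic.
#' wCV is reported under both divisor conventions (sqrt(2) and 2); the
#' `wcvDivisor` slot records which one `wcv` uses.
#'
#' @slot metric character(1), metric name (free-form label).
#' @slot n integer(1), number of paired subjects.
#' @slot meanPctDelta mean %-delta (%).
#' @slot sdPctDelta sample SD (n-1 denominator) of %-delta (%).
#' @slot wcv within-subject CV (%), `sdPctDelta / divisor`.
#' @slot wcvDivisor `"sqrt2"` or `"2"`.
#' @slot rc repeatability coefficient (%), exactly `1.96 * sdPctDelta`.
#' @slot lor numeric(2), limits of repeatability `meanPctDelta +/- rc`.
#' @slot meanAbsPctDelta mean of |%-delta| (%).
#' @slot normalityW Shapiro-Wilk W statistic (NA when n < 3).
#' @slot normalityP Shapiro-Wilk p-value (NA when n < 3).
#' @seealso [repeatabilitySummary()]
#' @exportClass RepeatabilitySummary
setClass("RepeatabilitySummary",
  representation(metric = "character", n = "integer",
                 meanPctDelta = "numeric", sdPctDelta = "numeric",
                 wcv = "numeric", wcvDivisor = "character", rc = "numeric",
                 lor = "numeric", meanAbsPctDelta = "numeric",
                 normalityW = "numeric", normalityP = "numeric"))

setValidity("RepeatabilitySummary", function(object) {
  msgs <- character(0)
  if (object@n < 2L) msgs <- c(msgs, "n must be >= 2")
  if (!isTRUE(all.equal(object@rc, 1.96 * object@sdPctDelta)))
    msgs <- c(msgs, "rc must equal 1.96 * sdPctDelta")
  if (length(object@lor) != 2L)
    msgs <- c(msgs, "lor must have length 2")
  if (!object@wcvDivisor %in% c("sqrt2", "2"))
    msgs <- c(msgs, "wcvDivisor must be 'sqrt2' or '2'")
  if (object@meanAbsPctDelta < abs(object@meanPctDelta) - 1e-8)
    msgs <- c(msgs, "mean |pct delta| cannot be below |mean pct delta|")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("VolumeImage %dx%dx%d [%s]\n", d[1], d[2], d[3],
              object@valueKind))
  cat(sprintf("  spacing: %.3g x %.3g x %.3g mm (voxel %.4g mL)\n",
              object@spacing[1], object@spacing[2], object@spacing[3],
              prod(object@spacing) / 1000))
  cat(sprintf("  range: [%.4g, %.4g]\n", min(object@values),
              max(object@values)))
  if (length(object@frameWindow) == 2L)
    cat(sprintf("  frame: %.1f-%.1f min post-injection\n",
                object@frameWindow[1], object@frameWindow[2]))
  invisible(NULL)
})

setMethod("show", "RoiMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("RoiMask %dx%dx%d: %d voxel(s), %.3g mL\n", d[1], d[2], d[3],
              sum(object@mask), sum(object@mask) *
                prod(object@spacing) / 1000))
  invisible(NULL)
})

setMethod("show", "SubjectRecord", function(object) {
  cat(sprintf(
    "SubjectRecord %s: %s, %.1f kg, %.1f cm, %.1f MBq, session %d, %s\n",
    object@subjectId, object@sex, object@weightKg, object@heightCm,
    object@injectedDoseMBq, object@session, object@modality))
  invisible(NULL)
})

setMethod("show", "MetricSet", function(object) {
  cat(sprintf("MetricSet [%s], %d metric(s)\n", object@valueKind,
              length(object@values)))
  if (length(object@values))
    print(round(object@values, 4))
  invisible(NULL)
})

setMethod("show", "RepeatabilitySummary", function(object) {
  cat(sprintf("RepeatabilitySummary '%s' (n = %d)\n", object@metric,
              object@n))
  cat(sprintf("  mean %%d = %.3f%%, SD = %.3f%%, mean |%%d| = %.3f%%\n",
              object@meanPctDelta, object@sdPctDelta,
              object@meanAbsPctDelta))
  cat(sprintf("  wCV = %.3f%% (divisor %s), RC = %.3f%%, LOR = [%.3f, %.3f]%%\n",
              object@wcv, object@wcvDivisor, object@rc, object@lor[1],
              object@lor[2]))
  if (is.finite(object@normalityP))
    cat(sprintf("  Shapiro-Wilk W = %.4f, p = %.4g\n", object@normalityW,
                object@normalityP))
  invisible(NULL)
})
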