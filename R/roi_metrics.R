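# Tumor metric extraction from a volume + whole-tumor mask. The "peak" of
# a lesion is the extremal mean over a 1-cm^3 sphere positioned with its
# center inside the contour (PERCIST-style); the sphere may extend beyond
# the contour but not beyond the image. ADC_trough is the min-mode mirror
# of the peak.

#' Build a discrete spherical kernel for peak/trough search
#'
#' The kernel is the set of integer voxel offsets whose centers lie within
#' the radius of a sphere of the target volume,
#' `r_mm = (3 V / (4 pi))^(1/3)` with V in mm^3 (6.204 mm for 1 mL).
#' Membership is binary by voxel-center inclusion (no partial-volume
#' weighting), so the realized kernel volume differs from the target by a
#' spacing-dependent discretization error, reported in the return value.
#'
#' @param spacing numeric(3), voxel spacing (dx, dy, dz) in mm.
#' @param targetVolumeML sphere volume in mL (default 1, the PERCIST
#'   convention).
#' @return A list with `offsets` (K x 3 integer matrix), `radiusMm`,
#'   `targetVolumeML`, `realizedVolumeML` (K x voxel volume) and
#'   `nVoxels`.
#' @export
sphereKernel <- function(spacing, targetVolumeML = 1.0) {
  stopifnot(length(spacing) == 3L, all(spacing > 0), targetVolumeML > 0)
  r <- (3 * targetVolumeML * 1000 / (4 * pi))^(1 / 3)
  half <- floor(r / spacing)
  g <- expand.grid(dx = -half[1]:half[1], dy = -half[2]:half[2],
                   dz = -half[3]:half[3])
  d2 <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 +
        (g$dz * spacing[3])^2
  offs <- as.matrix(g[d2 <= r^2, , drop = FALSE])
  dimnames(offs) <- NULL
  storage.mode(offs) <- "integer"
  # the center offset (0,0,0) is always within radius, so K >= 1; at very
  # coarse spacing the realized volume reports how bad the approximation is
  list(offsets = offs, radiusMm = r, targetVolumeML = targetVolumeML,
       realizedVolumeML = nrow(offs) * prod(spacing) / 1000,
       nVoxels = nrow(offs))
}

.maskedValues <- function(volume, mask) {
  checkSameGrid(volume, mask)
  if (voxelCount(mask) == 0L)
    stop("empty mask: no voxels to extract metrics from")
  volume@values[mask@mask]
}

#' In-mask extremum of a volume
#'
#' @param volume a [VolumeImage-class].
#' @param mask a nonempty [RoiMask-class] on the same grid.
#' @param mode `"max"` or `"min"`.
#' @return The extremal voxel value inside the mask.
#' @export
metricExtremum <- function(volume, mask, mode = c("max", "min")) {
  mode <- match.arg(mode)
  v <- .maskedValues(volume, mask)
  if (mode == "max") max(v) else min(v)
}

#' In-mask mean and median
#'
#' Median uses the even-count midpoint convention (average of the two
#' central order statistics).
#'
#' @inheritParams metricExtremum
#' @return Named numeric `c(mean = , median = )`.
#' @export
metricMeanMedian <- function(volume, mask) {
  v <- .maskedValues(volume, mask)
  c(mean = mean(v), median = stats::median(v))
}

#' Sphere-based peak (or trough) of a lesion
#'
#' Over all candidate sphere centers -- voxels whose centers lie inside
#' the mask and whose full kernel fits inside the image -- computes the
#' mean of the volume over the kernel, and returns the maximum
#' (`mode = "max"`, e.g. SUL_peak) or minimum (`mode = "min"`, e.g.
#' ADC_trough) such mean. Sphere voxels may extend outside the mask but
#' not outside the image. If no candidate center admits a full in-bounds
#' kernel, the kernel is clipped at the image border (mean over the
#' in-bounds voxels only) and the result is flagged `clipped = TRUE`.
#'
#' @inheritParams metricExtremum
#' @param kernel a kernel from [sphereKernel()]; default 1 mL at the
#'   volume's spacing.
#' @return A list with `value` (the extremal mean), `center` (integer(3)
#'   array index of the winning center), `clipped` (logical) and
#'   `kernel` (the kernel used).
#' @export
metricPeakSphere <- function(volume, mask, kernel = NULL,
                             mode = c("max", "min")) {
  mode <- match.arg(mode)
  checkSameGrid(volume, mask)
  if (voxelCount(mask) == 0L)
    stop("empty mask: no candidate sphere centers")
  if (is.null(kernel))
    kernel <- sphereKernel(volume@spacing)
  dims <- dim(volume@values)
  vals <- volume@values
  cand <- which(mask@mask, arr.ind = TRUE)
  nc <- nrow(cand)
  offs <- kernel$offsets
  K <- nrow(offs)
  sums <- numeric(nc)
  cnt <- integer(nc)
  for (k in seq_len(K)) {
    x <- cand[, 1] + offs[k, 1]
    y <- cand[, 2] + offs[k, 2]
    z <- cand[, 3] + offs[k, 3]
    inb <- x >= 1L & x <= dims[1] & y >= 1L & y <= dims[2] &
           z >= 1L & z <= dims[3]
    idx <- x[inb] + (y[inb] - 1L) * dims[1] +
           (z[inb] - 1L) * dims[1] * dims[2]
    sums[inb] <- sums[inb] + vals[idx]
    cnt[inb] <- cnt[inb] + 1L
  }
  full <- cnt == K
  if (any(full)) {
    means <- sums[full] / K
    sel <- if (mode == "max") which.max(means) else which.min(means)
    list(value = means[sel],
         center = as.integer(cand[which(full)[sel], ]),
         clipped = FALSE, kernel = kernel)
  } else {
    # no center fits the whole sphere: fall back to border-clipped means
    means <- sums / cnt
    sel <- if (mode == "max") which.max(means) else which.min(means)
    list(value = means[sel], center = as.integer(cand[sel, ]),
         clipped = TRUE, kernel = kernel)
  }
}

#' Percent-of-max isocontour within a whole-tumor contour
#'
#' Returns the mask of voxels inside `mask` whose value is at least
#' `fraction` times the in-mask maximum (inclusive threshold, so the
#' argmax voxel is always retained). All qualifying voxels are kept; with
#' `connected = TRUE` only the connected component(s) (6-connectivity)
#' containing an argmax voxel survive.
#'
#' @inheritParams metricExtremum
#' @param fraction threshold fraction of the in-mask max, in (0, 1];
#'   default 0.40.
#' @param connected keep only components containing an argmax voxel
#'   (default `FALSE`: the definition is purely threshold-based).
#' @return An [RoiMask-class].
#' @export
percentIsocontour <- function(volume, mask, fraction = 0.40,
                              connected = FALSE) {
  stopifnot(fraction > 0, fraction <= 1)
  v <- .maskedValues(volume, mask)
  mx <- max(v)
  if (mx <= 0)
    stop("in-mask maximum is non-positive; percent isocontour undefined")
  thr <- fraction * mx
  keep <- mask@mask & (volume@values >= thr)
  if (connected) {
    lab <- .labelComponents6(keep)
    argmax <- keep & (volume@values >= mx)
    keepLabs <- unique(lab[argmax])
    keep <- array(lab %in% keepLabs[keepLabs > 0L], dim(keep))
  }
  RoiMask(keep, spacing = mask@spacing)
}

# 6-connectivity flood labeling, used only by the optional component
# filter of percentIsocontour.
.labelComponents6 <- function(b) {
  dims <- dim(b)
  lab <- array(0L, dims)
  nextLab <- 0L
  idxAll <- which(b)
  for (seed in idxAll) {
    if (lab[seed] != 0L) next
    nextLab <- nextLab + 1L
    queue <- seed
    lab[seed] <- nextLab
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      ai <- arrayInd(cur, dims)
      for (d in 1:3) for (s in c(-1L, 1L)) {
        nb <- ai
        nb[, d] <- nb[, d] + s
        ok <- nb[, d] >= 1L & nb[, d] <= dims[d]
        if (!any(ok)) next
        lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] +
               (nb[ok, 3] - 1L) * dims[1] * dims[2]
        lin <- lin[b[lin] & lab[lin] == 0L]
        if (length(lin)) {
          lab[lin] <- nextLab
          queue <- c(queue, lin)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

#' Volume of a mask in mL
#'
#' Voxel count times voxel volume; 0 for an empty mask.
#'
#' @param mask an [RoiMask-class].
#' @return Volume in mL.
#' @export
roiVolume <- function(mask) {
  voxelCount(mask) * voxelVolume(mask)
}

#' Total lesion glycolysis
#'
#' `mean(in-mask SUV) * mask volume [mL]`, equivalently
#' `sum(in-mask SUV) * voxel volume`. Accepts SUV or SUL volumes.
#'
#' @param volume a [VolumeImage-class] with value kind `SUV_g_per_mL` or
#'   `SUL_g_per_mL`.
#' @param mask a nonempty [RoiMask-class].
#' @return TLG in g.
#' @export
totalLesionGlycolysis <- function(volume, mask) {
  if (!valueKind(volume) %in% c("SUV_g_per_mL", "SUL_g_per_mL"))
    stop("total lesion glycolysis requires an SUV or SUL volume")
  v <- .maskedValues(volume, mask)
  sum(v) * voxelVolume(mask)
}

# metric name -> value kinds it is defined for
.METRIC_KINDS <- list(
  suv_max = "SUV_g_per_mL", suv_mean = "SUV_g_per_mL",
  suv_median = "SUV_g_per_mL", suv_peak = "SUV_g_per_mL",
  sul_peak = "SUL_g_per_mL", sul_max = "SUL_g_per_mL",
  metabolic_tumor_volume_mL = c("SUV_g_per_mL", "SUL_g_per_mL"),
  total_lesion_glycolysis_g = c("SUV_g_per_mL", "SUL_g_per_mL"),
  adc_max = "ADC_1e-3_mm2_per_s", adc_min = "ADC_1e-3_mm2_per_s",
  adc_mean = "ADC_1e-3_mm2_per_s", adc_median = "ADC_1e-3_mm2_per_s",
  adc_trough = "ADC_1e-3_mm2_per_s",
  diffusional_tumor_volume_mL = "ADC_1e-3_mm2_per_s")

#' Metric names supported for a value kind
#'
#' @param kind a value kind (see [VolumeImage-class]).
#' @return Character vector of metric names.
#' @export
supportedMetrics <- function(kind) {
  names(.METRIC_KINDS)[vapply(.METRIC_KINDS, function(k) kind %in% k,
                              logical(1))]
}

#' Extract a set of named metrics from one volume + mask
#'
#' Each requested metric must be compatible with the volume's value kind
#' (e.g. `adc_trough` only on ADC maps); incompatible requests error.
#' Peak/trough metrics use a 1-cm^3 sphere search ([metricPeakSphere()]);
#' tumor volumes are the whole-contour volume; TLG is mean x volume.
#'
#' @inheritParams metricExtremum
#' @param metrics character vector of metric names; default: all metrics
#'   supported for the volume's value kind.
#' @return A [MetricSet-class].
#' @export
extractMetricSet <- function(volume, mask, metrics = NULL) {
  checkSameGrid(volume, mask)
  if (voxelCount(mask) == 0L)
    stop("empty mask: no voxels to extract metrics from")
  kind <- valueKind(volume)
  if (is.null(metrics))
    metrics <- supportedMetrics(kind)
  bad <- setdiff(metrics, names(.METRIC_KINDS))
  if (length(bad))
    stop("unknown metric(s): ", paste(bad, collapse = ", "))
  incompat <- metrics[!vapply(.METRIC_KINDS[metrics],
                              function(k) kind %in% k, logical(1))]
  if (length(incompat))
    stop("metric(s) ", paste(incompat, collapse = ", "),
         " undefined for value kind '", kind, "'")
  out <- numeric(0)
  details <- list()
  mm <- NULL
  for (m in metrics) {
    val <- switch(m,
      suv_max = , sul_max = , adc_max =
        metricExtremum(volume, mask, "max"),
      adc_min = metricExtremum(volume, mask, "min"),
      suv_mean = , adc_mean = {
        if (is.null(mm)) mm <- metricMeanMedian(volume, mask)
        mm[["mean"]]
      },
      suv_median = , adc_median = {
        if (is.null(mm)) mm <- metricMeanMedian(volume, mask)
        mm[["median"]]
      },
      suv_peak = , sul_peak = {
        pk <- metricPeakSphere(volume, mask, mode = "max")
        details[[m]] <- pk[c("center", "clipped")]
        pk$value
      },
      adc_trough = {
        pk <- metricPeakSphere(volume, mask, mode = "min")
        details[[m]] <- pk[c("center", "clipped")]
        pk$value
      },
      metabolic_tumor_volume_mL = , diffusional_tumor_volume_mL =
        roiVolume(mask),
      total_lesion_glycolysis_g = totalLesionGlycolysis(volume, mask))
    out[m] <- val
  }
  new("MetricSet", values = out, valueKind = kind, details = details)
}
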