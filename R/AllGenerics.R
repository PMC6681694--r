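#' Accessors for image and result containers
#'
#' `imgValues` returns the raw 3D array; `imgSpacing` the voxel spacing in
#' mm; `voxelVolume` the volume of one voxel in mL (`dx*dy*dz/1000`);
#' `valueKind` the declared physical quantity; `maskArray` the logical
#' array of an [RoiMask-class]; `voxelCount` its number of set voxels;
#' `metricValues` the named metric vector of a [MetricSet-class].
#'
#' @param x a [VolumeImage-class], [RoiMask-class] or [MetricSet-class].
#' @return See details above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imgValues", function(x) standardGeneric("imgValues"))
#' @rdname accessors
#' @export
setGeneric("imgSpacing", function(x) standardGeneric("imgSpacing"))
#' @rdname accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))
#' @rdname accessors
#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))
#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))
#' @rdname accessors
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' @rdname accessors
setMethod("imgValues", "VolumeImage", function(x) x@values)
#' @rdname accessors
setMethod("imgSpacing", "VolumeImage", function(x) x@spacing)
#' @rdname accessors
setMethod("imgSpacing", "RoiMask", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelVolume", "VolumeImage", function(x) prod(x@spacing) / 1000)
#' @rdname accessors
setMethod("voxelVolume", "RoiMask", function(x) prod(x@spacing) / 1000)
#' @rdname accessors
setMethod("valueKind", "VolumeImage", function(x) x@valueKind)
#' @rdname accessors
setMethod("valueKind", "MetricSet", function(x) x@valueKind)
#' @rdname accessors
setMethod("maskArray", "RoiMask", function(x) x@mask)
#' @rdname accessors
setMethod("voxelCount", "RoiMask", function(x) sum(x@mask))
#' @rdname accessors
setMethod("metricValues", "MetricSet", function(x) x@values)

#' Coerce a RepeatabilitySummary to a one-row data frame
#'
#' Reports wCV under both divisor conventions side by side
#' (`wcv_sqrt2`, `wcv_2`), alongside the convention selected at
#' construction (`wcv`, `wcv_divisor`).
#'
#' @param x a [RepeatabilitySummary-class].
#' @param row.names,optional,... ignored (S3 signature compatibility).
#' @return A one-row `data.frame`.
#' @export
as.data.frame.RepeatabilitySummary <- function(x, row.names = NULL,
                                               optional = FALSE, ...) {
  data.frame(
    metric = x@metric, n = x@n,
    mean_pct_delta = x@meanPctDelta, sd_pct_delta = x@sdPctDelta,
    wcv = x@wcv, wcv_divisor = x@wcvDivisor,
    wcv_sqrt2 = x@sdPctDelta / sqrt(2), wcv_2 = x@sdPctDelta / 2,
    rc = x@rc, lor_lower = x@lor[1], lor_upper = x@lor[2],
    mean_abs_pct_delta = x@meanAbsPctDelta,
    normality_W = x@normalityW, normality_p = x@normalityP,
    stringsAsFactors = FALSE)
}
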