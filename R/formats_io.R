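# Volumes and masks are NIfTI (.nii / .nii.gz); subject metadata is JSON;
# result tables are CSV. Arrays are kept in native NIfTI index order
# (x, y, z) with spacing (dx, dy, dz) in mm; no world-space affine math is
# performed beyond spacing (single-station axial volumes).

#' Read a 3D volume from a NIfTI file
#'
#' Loads a `.nii`/`.nii.gz` image into a [VolumeImage-class], taking the
#' voxel spacing from the file header. The image must have exactly 3
#' spatial dimensions and contain no non-finite voxels; violations raise
#' an error (with the NaN count, when applicable) rather than being
#' silently repaired.
#'
#' @param path path to a NIfTI file.
#' @param valueKind the physical quantity stored in the file; see
#'   [VolumeImage-class].
#' @param frameWindow optional numeric(2) reconstruction window, minutes
#'   post-injection.
#' @return A [VolumeImage-class].
#' @seealso [writeVolume()], [readMask()]
#' @export
readVolume <- function(path, valueKind, frameWindow = numeric(0)) {
  if (!file.exists(path))
    stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), " dimensions in ", path)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-positive voxel spacing in header of ", path)
  vals <- array(as.numeric(img), d)
  nbad <- sum(!is.finite(vals))
  if (nbad > 0L)
    stop(nbad, " non-finite voxel(s) in ", path)
  VolumeImage(vals, spacing = sp, valueKind = valueKind,
              frameWindow = frameWindow)
}

#' Write a VolumeImage (or RoiMask) to a NIfTI file
#'
#' @param x a [VolumeImage-class] or [RoiMask-class].
#' @param path destination `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(x, path) {
  if (is(x, "RoiMask")) {
    vals <- array(as.integer(x@mask), dim(x@mask))
    sp <- x@spacing
  } else if (is(x, "VolumeImage")) {
    vals <- x@values
    sp <- x@spacing
  } else stop("x must be a VolumeImage or RoiMask")
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check that two objects share a voxel grid
#'
#' Downstream metric extraction refuses grid mismatches rather than
#' resampling; this is the shared gate.
#'
#' @param a,b [VolumeImage-class] or [RoiMask-class] objects.
#' @param tol relative spacing tolerance.
#' @return `TRUE` invisibly, or an error.
#' @export
checkSameGrid <- function(a, b, tol = 1e-4) {
  da <- if (is(a, "RoiMask")) dim(a@mask) else dim(a@values)
  db <- if (is(b, "RoiMask")) dim(b@mask) else dim(b@values)
  if (!identical(da, db))
    stop("grid shape mismatch: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  sa <- imgSpacing(a); sb <- imgSpacing(b)
  if (any(abs(sa - sb) > tol * pmax(sa, sb)))
    stop("voxel spacing mismatch: (", paste(signif(sa, 6), collapse = ", "),
         ") vs (", paste(signif(sb, 6), collapse = ", "), ")")
  invisible(TRUE)
}

#' Read an ROI mask from a NIfTI file
#'
#' Any nonzero voxel becomes `TRUE`. The mask grid must match the
#' reference volume's shape exactly and spacing within `tol`. An empty
#' mask is permitted at load time (with a warning); metric extraction on
#' an empty mask errors.
#'
#' @param path path to a NIfTI mask file.
#' @param reference the [VolumeImage-class] whose grid the mask must share.
#' @param tol relative spacing tolerance.
#' @return An [RoiMask-class].
#' @export
readMask <- function(path, reference, tol = 1e-4) {
  if (!file.exists(path))
    stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D mask, got ", length(d), " dimensions in ", path)
  sp <- RNifti::pixdim(img)[1:3]
  m <- RoiMask(array(as.numeric(img) != 0, d), spacing = sp)
  checkSameGrid(m, reference, tol = tol)
  if (voxelCount(m) == 0L)
    warning("mask is empty: ", path)
  m
}

#' Read/write per-session subject metadata as JSON
#'
#' The JSON schema has keys `subject_id`, `sex`, `weight_kg`, `height_cm`,
#' `injected_dose_MBq`, `injection_time_min`, `session`, `modality`
#' matching the [SubjectRecord-class] slots. Timestamps are minutes
#' post-injection (floats), pre-converted by whoever writes the file.
#'
#' @param path JSON file path.
#' @return `readSubjectRecord` returns a [SubjectRecord-class];
#'   `writeSubjectRecord` returns `path` invisibly.
#' @export
readSubjectRecord <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("subject_id", "sex", "weight_kg", "height_cm",
            "injected_dose_MBq")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop("subject record ", path, " missing field(s): ",
         paste(miss, collapse = ", "))
  SubjectRecord(rec$subject_id, rec$sex, rec$weight_kg, rec$height_cm,
                rec$injected_dose_MBq,
                injectionTimeMin = rec$injection_time_min %||% 0,
                session = rec$session %||% 1L,
                modality = rec$modality %||% "PETCT")
}

#' @rdname readSubjectRecord
#' @param x a [SubjectRecord-class].
#' @export
writeSubjectRecord <- function(x, path) {
  jsonlite::write_json(list(
    subject_id = x@subjectId, sex = x@sex, weight_kg = x@weightKg,
    height_cm = x@heightCm, injected_dose_MBq = x@injectedDoseMBq,
    injection_time_min = x@injectionTimeMin, session = x@session,
    modality = x@modality), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write (and re-read) a results table as CSV
#'
#' Rows share one schema; an empty data frame yields a header-only file.
#' Numeric columns survive a round trip at full double precision
#' (15 significant digits).
#'
#' @param rows a `data.frame`.
#' @param path destination CSV path.
#' @return `writeResultsTable`: `path` invisibly. `readResultsTable`: the
#'   `data.frame`.
#' @export
writeResultsTable <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResultsTable
#' @export
readResultsTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
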