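# Geometry-faithful conversion between DICOM series, in-memory volumes and
# NIfTI files. Internal patient coordinates are LPS (DICOM); NIfTI affines
# are RAS, obtained by negating the first two coordinate axes.

.geometry_error <- function(...) {
  stop(errorCondition(sprintf(...), class = c("ctqv_geometry_error", "ctqv_error")))
}

#' Sort a DICOM series into slice order
#'
#' Orders instances by ascending scalar projection of Image Position
#' (Patient) onto the slice normal (row direction x column direction), with
#' ties broken by instance number then SOP instance UID.
#'
#' @param instances List of [dicom_instance_record()] from one series.
#' @return The same list, ordered.
#' @export
sort_series <- function(instances) {
  stopifnot(length(instances) >= 1L)
  series <- unique(vapply(instances, function(r) r$series_instance_uid, ""))
  if (length(series) != 1L) .geometry_error("instances span multiple series")
  iop0 <- instances[[1]]$image_orientation_patient
  if (is.null(iop0)) .geometry_error("missing ImageOrientationPatient")
  for (r in instances) {
    if (is.null(r$image_orientation_patient) ||
        max(abs(r$image_orientation_patient - iop0)) > 1e-4) {
      .geometry_error("mixed image orientations within one series")
    }
    if (is.null(r$image_position_patient)) {
      .geometry_error("missing ImagePositionPatient on instance %s", r$sop_instance_uid)
    }
  }
  normal <- .cross3(iop0[1:3], iop0[4:6])
  proj <- vapply(instances, function(r) sum(r$image_position_patient * normal), 0)
  inst_no <- vapply(instances, function(r) {
    if (is.na(r$instance_number)) .Machine$integer.max else r$instance_number
  }, 1L)
  sop <- vapply(instances, function(r) r$sop_instance_uid, "")
  instances[order(proj, inst_no, sop)]
}

#' Geometry of a sorted DICOM series
#'
#' Validates uniform in-plane metadata and inter-slice spacing (every
#' position increment within 10% of the median increment) and assembles the
#' [volume_geometry()]. A single-slice series falls back to SliceThickness
#' for the inter-slice spacing.
#'
#' @param instances Output of [sort_series()].
#' @return A [volume_geometry()].
#' @export
series_geometry <- function(instances) {
  stopifnot(length(instances) >= 1L)
  first <- instances[[1]]
  rows <- first$rows; cols <- first$columns; ps <- first$pixel_spacing
  if (is.na(rows) || is.na(cols) || is.null(ps)) {
    .geometry_error("missing Rows/Columns/PixelSpacing")
  }
  for (r in instances) {
    if (!identical(r$rows, rows) || !identical(r$columns, cols) ||
        max(abs(r$pixel_spacing - ps)) > 1e-6) {
      .geometry_error("non-uniform Rows/Columns/PixelSpacing across slices")
    }
  }
  iop <- first$image_orientation_patient
  normal <- .cross3(iop[1:3], iop[4:6])
  n <- length(instances)
  proj <- vapply(instances, function(r) sum(r$image_position_patient * normal), 0)
  if (n > 1L) {
    inc <- diff(proj)
    med <- stats::median(inc)
    if (med <= 0) .geometry_error("slice positions are not strictly increasing")
    bad <- which(abs(inc - med) > 0.1 * med)
    if (length(bad)) {
      .geometry_error("non-uniform inter-slice spacing: gap %.4g mm between slices %d and %d (median %.4g mm)",
                      inc[bad[1]], bad[1], bad[1] + 1L, med)
    }
    slice_spacing <- med
  } else {
    st <- first$slice_thickness
    if (is.null(st) || !length(st)) {
      .geometry_error("single-slice series with no SliceThickness")
    }
    slice_spacing <- as.numeric(st[1])
  }
  volume_geometry(origin = first$image_position_patient,
                  row_direction = iop[1:3],
                  column_direction = iop[4:6],
                  spacing = c(ps[1], ps[2], slice_spacing),
                  shape = c(rows, cols, n))
}

#' Assemble an image volume from a sorted DICOM series
#'
#' Stored pixel values are mapped to HU via the rescale transform
#' `HU = stored * slope + intercept`. Inter-slice spacing is the median of
#' consecutive slice-position increments (each increment must lie within 10%
#' of the median); the Spacing Between Slices tag is deliberately ignored
#' when positions exist. A single-slice series falls back to SliceThickness.
#'
#' @param instances Output of [sort_series()].
#' @return An [image_volume()].
#' @export
build_volume <- function(instances) {
  geom <- series_geometry(instances)
  rows <- geom$shape[1]; cols <- geom$shape[2]; n <- geom$shape[3]
  voxels <- array(0, dim = c(rows, cols, n))
  for (k in seq_len(n)) {
    rec <- instances[[k]]
    signed <- identical(as.integer(ds_get(rec$dataset, "PixelRepresentation", 0L)), 1L)
    vals <- readBin(rec$pixel_payload, integer(), n = rows * cols, size = 2,
                    endian = "little", signed = signed)
    voxels[, , k] <- t(matrix(vals, nrow = cols)) * rec$rescale_slope + rec$rescale_intercept
  }
  image_volume(voxels, geom, source_series_uid = instances[[1]]$series_instance_uid)
}

#' NIfTI (RAS) affine of a volume geometry
#' @param geom A [volume_geometry()].
#' @return 4x4 affine mapping 0-based (row, col, slice) indices to RAS mm.
#' @export
nifti_affine <- function(geom) {
  flip <- c(-1, -1, 1)
  cbind(rbind(cbind(geom$column_direction * geom$spacing[1] * flip,
                    geom$row_direction * geom$spacing[2] * flip,
                    geom$slice_direction * geom$spacing[3] * flip),
              0),
        c(geom$origin * flip, 1))
}

#' Recover an LPS volume geometry from a NIfTI affine
#' @param affine 4x4 RAS affine.
#' @param shape Integer 3-vector (rows, cols, slices).
#' @return A [volume_geometry()].
#' @export
geometry_from_affine <- function(affine, shape) {
  flip <- c(-1, -1, 1)
  sp <- apply(affine[1:3, 1:3], 2, function(v) sqrt(sum(v^2)))
  volume_geometry(origin = affine[1:3, 4] * flip,
                  row_direction = affine[1:3, 2] * flip / sp[2],
                  column_direction = affine[1:3, 1] * flip / sp[1],
                  slice_direction = affine[1:3, 3] * flip / sp[3],
                  spacing = sp,
                  shape = shape)
}

.write_nifti_array <- function(arr, geom, path, datatype) {
  img <- RNifti::asNifti(arr)
  aff <- nifti_affine(geom)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 1L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write an image volume as NIfTI-1
#'
#' The affine maps voxel indices to RAS patient coordinates (LPS with the
#' first two axes negated).
#'
#' @param volume An [image_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  .write_nifti_array(volume$voxels, volume$geometry, path, datatype = "double")
}

#' Write a label volume as NIfTI-1
#' @param labels A [label_volume()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nifti_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  .write_nifti_array(labels$labels, labels$geometry, path, datatype = "int32")
}

#' Read a NIfTI image volume back
#' @param path NIfTI file.
#' @param source_series_uid Optional series UID to attach.
#' @return An [image_volume()].
#' @export
read_nifti_volume <- function(path, source_series_uid = NA_character_) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  geom <- geometry_from_affine(unclass(aff)[1:4, 1:4], dim(arr))
  image_volume(arr, geom, source_series_uid)
}

#' Read and validate a segmentation mask written by a backend
#'
#' The mask must be co-registered to the source series: its shape must equal
#' the expected geometry's shape and its affine (after RAS to LPS) must match
#' within 1e-3 mm. Values must be non-negative integers (reals within 1e-6
#' of an integer are rounded).
#'
#' @param path NIfTI label file.
#' @param expected_geometry The source volume's [volume_geometry()].
#' @return A [label_volume()] on `expected_geometry`.
#' @export
read_nifti_labels <- function(path, expected_geometry) {
  stopifnot(inherits(expected_geometry, "volume_geometry"))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (!identical(as.integer(dim(arr)), expected_geometry$shape)) {
    stop(errorCondition(sprintf(
      "mask shape (%s) does not match source series shape (%s)",
      paste(dim(arr), collapse = "x"),
      paste(expected_geometry$shape, collapse = "x")),
      class = c("ctqv_shape_mismatch", "ctqv_error")))
  }
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))[1:4, 1:4]
  got <- geometry_from_affine(aff, dim(arr))
  if (!geom_equal(got, expected_geometry, tol = 1e-3)) {
    stop(errorCondition("mask affine does not match the source series geometry",
                        class = c("ctqv_affine_mismatch", "ctqv_error")))
  }
  if (any(arr < -1e-6)) {
    stop(errorCondition("mask contains negative labels",
                        class = c("ctqv_label_value_error", "ctqv_error")))
  }
  rounded <- round(arr)
  if (max(abs(arr - rounded)) > 1e-6) {
    stop(errorCondition("mask contains non-integer labels",
                        class = c("ctqv_label_value_error", "ctqv_error")))
  }
  label_volume(array(as.integer(rounded), dim = dim(arr)), expected_geometry)
}
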