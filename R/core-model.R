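# Domain types shared across the pipeline: volume geometry, image and label
# volumes, segment descriptors, and the de-identification profile.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) v / sqrt(sum(v^2))

#' Volume geometry: the index to patient-coordinate mapping
#'
#' The single source of truth for mapping voxel indices to patient
#' coordinates. Coordinates are LPS (the DICOM convention), millimetres.
#' Voxel indices are 0-based and `origin` is the patient position of the
#' *center* of voxel (0,0,0), i.e. Image Position (Patient) of the first
#' slice. `row_direction` is the direction along an image row (increasing
#' column index); `column_direction` is the direction down a column
#' (increasing row index); `slice_direction = row_direction x
#' column_direction` up to sign.
#'
#' @param origin Numeric 3-vector, mm (LPS).
#' @param row_direction,column_direction Unit 3-vectors, mutually orthogonal
#'   within 1e-4.
#' @param spacing Numeric 3-vector: (between-rows, between-columns,
#'   between-slices) spacing in mm, all > 0.
#' @param shape Integer 3-vector: (n_rows, n_cols, n_slices).
#' @param slice_direction Optional unit 3-vector; defaults to
#'   `row_direction x column_direction`. Must match the cross product up to
#'   sign within 1e-4.
#' @return A `volume_geometry` object.
#' @export
volume_geometry <- function(origin, row_direction, column_direction, spacing, shape,
                            slice_direction = NULL) {
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  row_direction <- as.numeric(row_direction)
  column_direction <- as.numeric(column_direction)
  shape <- as.integer(shape)
  stopifnot(length(origin) == 3L, length(spacing) == 3L, length(shape) == 3L)
  if (any(spacing <= 0)) stop("all spacings must be > 0", call. = FALSE)
  if (any(shape <= 0L)) stop("all shape entries must be > 0", call. = FALSE)
  tol <- 1e-4
  if (abs(sqrt(sum(row_direction^2)) - 1) > tol ||
      abs(sqrt(sum(column_direction^2)) - 1) > tol) {
    stop("direction cosines must be unit vectors", call. = FALSE)
  }
  if (abs(sum(row_direction * column_direction)) > tol) {
    stop("row and column directions must be orthogonal", call. = FALSE)
  }
  normal <- .cross3(row_direction, column_direction)
  if (is.null(slice_direction)) {
    slice_direction <- normal
  } else {
    slice_direction <- as.numeric(slice_direction)
    if (min(sqrt(sum((slice_direction - normal)^2)),
            sqrt(sum((slice_direction + normal)^2))) > tol) {
      stop("slice_direction must equal row x column direction up to sign", call. = FALSE)
    }
  }
  structure(list(origin = origin,
                 row_direction = .unit(row_direction),
                 column_direction = .unit(column_direction),
                 slice_direction = .unit(slice_direction),
                 spacing = spacing,
                 shape = shape),
            class = "volume_geometry")
}

#' Patient coordinates of voxel centers
#'
#' @param geom A [volume_geometry()].
#' @param idx Integer matrix (n x 3) of 0-based (row, col, slice) indices.
#' @return n x 3 matrix of LPS coordinates in mm.
#' @export
voxel_to_patient <- function(geom, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  basis <- cbind(geom$column_direction * geom$spacing[1],
                 geom$row_direction * geom$spacing[2],
                 geom$slice_direction * geom$spacing[3])
  sweep(idx %*% t(basis), 2L, geom$origin, "+")
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat("<volume_geometry>\n")
  cat(sprintf("  shape   : %d x %d x %d (rows x cols x slices)\n",
              x$shape[1], x$shape[2], x$shape[3]))
  cat(sprintf("  spacing : %.4g x %.4g x %.4g mm\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin  : (%.2f, %.2f, %.2f) mm LPS\n",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

geom_equal <- function(a, b, tol = 1e-3) {
  all(abs(a$origin - b$origin) <= tol) &&
    all(abs(a$row_direction - b$row_direction) <= tol) &&
    all(abs(a$column_direction - b$column_direction) <= tol) &&
    all(abs(a$slice_direction - b$slice_direction) <= tol) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    identical(a$shape, b$shape)
}

#' A CT image volume in Hounsfield units
#'
#' @param voxels 3-D numeric array (rows x cols x slices), HU.
#' @param geometry A [volume_geometry()] matching `dim(voxels)`.
#' @param source_series_uid UID of the DICOM series the volume came from.
#' @return An `image_volume`.
#' @export
image_volume <- function(voxels, geometry, source_series_uid = NA_character_) {
  stopifnot(inherits(geometry, "volume_geometry"))
  if (!identical(dim(voxels), as.integer(geometry$shape))) {
    stop("voxel array shape does not match geometry shape", call. = FALSE)
  }
  if (!all(is.finite(voxels))) stop("HU values must be finite", call. = FALSE)
  structure(list(voxels = voxels, geometry = geometry,
                 source_series_uid = source_series_uid),
            class = "image_volume")
}

#' An integer label map co-registered with its source image volume
#'
#' @param labels 3-D non-negative integer array; 0 is background.
#' @param geometry A [volume_geometry()] matching `dim(labels)`.
#' @return A `label_volume` with `label_ids_present` computed.
#' @export
label_volume <- function(labels, geometry) {
  stopifnot(inherits(geometry, "volume_geometry"))
  if (!identical(dim(labels), as.integer(geometry$shape))) {
    stop("label array shape does not match geometry shape", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be non-negative", call. = FALSE)
  ids <- sort(unique(as.vector(labels)))
  structure(list(labels = labels, geometry = geometry,
                 label_ids_present = ids[ids > 0L]),
            class = "label_volume")
}

#' Per-segment semantics for SEG encoding
#'
#' Mirrors one entry of a dcmqi-style segment-attributes JSON: what the
#' segment is (coded category and type), how to display it, and which
#' algorithm produced it.
#'
#' @param label_id Integer > 0; the value in the label map this segment maps.
#' @param segment_label Human-readable label (e.g. "pelvic hematoma").
#' @param category_code,type_code Character 3-vectors
#'   `(code_value, coding_scheme, code_meaning)`.
#' @param display_color_rgb Integer 3-vector in 0..255.
#' @param algorithm_type One of "AUTOMATIC", "SEMIAUTOMATIC", "MANUAL".
#' @param algorithm_name Free text naming the algorithm.
#' @return A `segment_descriptor`.
#' @export
segment_descriptor <- function(label_id, segment_label,
                               category_code = c("M-01000", "SRT", "Morphologically Altered Structure"),
                               type_code = c("M-35000", "SRT", "Hemorrhage"),
                               display_color_rgb = c(216L, 38L, 38L),
                               algorithm_type = "AUTOMATIC",
                               algorithm_name = "ctqv") {
  label_id <- as.integer(label_id)
  if (label_id <= 0L) stop("label_id must be > 0", call. = FALSE)
  check_code <- function(code, what) {
    code <- as.character(code)
    if (length(code) != 3L || any(!nzchar(code))) {
      stop(what, " must be a non-empty (value, scheme, meaning) triple", call. = FALSE)
    }
    code
  }
  algorithm_type <- match.arg(algorithm_type, c("AUTOMATIC", "SEMIAUTOMATIC", "MANUAL"))
  rgb <- as.integer(display_color_rgb)
  if (length(rgb) != 3L || any(rgb < 0L) || any(rgb > 255L)) {
    stop("display_color_rgb must be three integers in 0..255", call. = FALSE)
  }
  structure(list(label_id = label_id,
                 segment_label = as.character(segment_label),
                 category_code = check_code(category_code, "category_code"),
                 type_code = check_code(type_code, "type_code"),
                 display_color_rgb = rgb,
                 algorithm_type = algorithm_type,
                 algorithm_name = as.character(algorithm_name)),
            class = "segment_descriptor")
}

.check_descriptors <- function(descriptors) {
  stopifnot(length(descriptors) >= 1L,
            all(vapply(descriptors, inherits, TRUE, "segment_descriptor")))
  ids <- vapply(descriptors, function(d) d$label_id, 1L)
  if (anyDuplicated(ids)) stop("duplicate label_id in descriptor collection", call. = FALSE)
  descriptors[order(ids)]
}

# Tags that must never be touched by de-identification: they carry the
# geometry and signal that volumetry depends on.
.GEOMETRY_TAGS <- vapply(c(
  "ImagePositionPatient", "ImageOrientationPatient", "PixelSpacing",
  "SliceThickness", "SpacingBetweenSlices", "SliceLocation",
  "RescaleSlope", "RescaleIntercept", "Rows", "Columns",
  "BitsAllocated", "BitsStored", "HighBit", "PixelRepresentation",
  "SamplesPerPixel", "PhotometricInterpretation", "PixelData"
), dcm_tag, "")

#' A de-identification profile
#'
#' A documented subset of the DICOM Basic Confidentiality Profile: tags in
#' `remove_tags` are deleted, `replace_tags` values are substituted, all
#' Study/Series/SOP/FrameOfReference UIDs are remapped through the session
#' [uid_map()] when `remap_uids`, dates are coarsened to year precision when
#' `coarsen_dates`, and private tags are stripped when `strip_private`.
#' Geometry tags (position, orientation, spacing, rescale, pixel data) are
#' always retained and may not appear in the profile.
#'
#' @param remove_tags Character vector of keywords or hex tags to delete.
#' @param replace_tags Named list: keyword -> replacement value.
#' @param remap_uids,coarsen_dates,strip_private Logical switches.
#' @return An `anonymization_profile`.
#' @export
anonymization_profile <- function(remove_tags = character(),
                                  replace_tags = list(),
                                  remap_uids = TRUE,
                                  coarsen_dates = TRUE,
                                  strip_private = TRUE) {
  remove_tags <- vapply(remove_tags, dcm_tag, "")
  if (length(replace_tags)) {
    names(replace_tags) <- vapply(names(replace_tags), dcm_tag, "")
  }
  touched <- c(remove_tags, names(replace_tags))
  bad <- intersect(touched, .GEOMETRY_TAGS)
  if (length(bad)) {
    stop("profile must not touch geometry tags: ",
         paste(.dcm_keyword_by_tag[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(remove_tags = unname(remove_tags),
                 replace_tags = replace_tags,
                 remap_uids = isTRUE(remap_uids),
                 coarsen_dates = isTRUE(coarsen_dates),
                 strip_private = isTRUE(strip_private),
                 retain_geometry = TRUE),
            class = "anonymization_profile")
}

#' The default de-identification profile
#'
#' Removes the minimal identity-bearing set (patient name/ID/birth date/
#' address/phone, other patient IDs, institution and operator names,
#' referring physician, accession number), marks PatientIdentityRemoved,
#' remaps all UIDs, coarsens dates to year precision, and strips private
#' tags. Burned-in pixel annotations are NOT handled.
#'
#' @return An [anonymization_profile()].
#' @export
default_anonymization_profile <- function() {
  anonymization_profile(
    remove_tags = c("PatientName", "PatientID", "PatientBirthDate",
                    "PatientAddress", "PatientTelephoneNumbers",
                    "OtherPatientIDs", "InstitutionName", "InstitutionAddress",
                    "InstitutionalDepartmentName", "OperatorsName",
                    "ReferringPhysicianName", "AccessionNumber"),
    replace_tags = list(PatientIdentityRemoved = "YES",
                        DeidentificationMethod = "ctqv basic-profile subset"),
    remap_uids = TRUE,
    coarsen_dates = TRUE,
    strip_private = TRUE
  )
}
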