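# DicomInstanceRecord: a validated view over one received DICOM object,
# plus the de-identification operation.

.IDENTITY_UID_TAGS <- vapply(c("StudyInstanceUID", "SeriesInstanceUID",
                               "SOPInstanceUID", "FrameOfReferenceUID",
                               "MediaStorageSOPInstanceUID"), dcm_tag, "")

#' Build an instance record from a parsed DICOM dataset
#'
#' Extracts and validates the identifying UIDs, geometry tags and pixel
#' metadata of one image object. The full dataset travels with the record
#' (field `dataset`) and is the pixel payload reference.
#'
#' @param ds A `dcm_dataset` (from [dcm_read()]).
#' @return A `dicom_instance_record`.
#' @export
dicom_instance_record <- function(ds) {
  stopifnot(inherits(ds, "dcm_dataset"))
  sop <- ds_get(ds, "SOPInstanceUID"); series <- ds_get(ds, "SeriesInstanceUID")
  study <- ds_get(ds, "StudyInstanceUID")
  for (u in list(c(sop, "SOPInstanceUID"), c(series, "SeriesInstanceUID"),
                 c(study, "StudyInstanceUID"))) {
    if (is.null(u[1]) || !is_valid_uid(u[1])) {
      stop("invalid or missing ", u[2], call. = FALSE)
    }
  }
  iop <- ds_get(ds, "ImageOrientationPatient")
  if (!is.null(iop)) {
    if (length(iop) != 6L) stop("ImageOrientationPatient must have 6 values", call. = FALSE)
    r <- iop[1:3]; c_ <- iop[4:6]
    if (abs(sqrt(sum(r^2)) - 1) > 1e-4 || abs(sqrt(sum(c_^2)) - 1) > 1e-4 ||
        abs(sum(r * c_)) > 1e-4) {
      stop("ImageOrientationPatient rows must be orthonormal", call. = FALSE)
    }
  }
  ps <- ds_get(ds, "PixelSpacing")
  if (!is.null(ps) && any(ps <= 0)) stop("PixelSpacing must be > 0", call. = FALSE)

  id_tags <- intersect(names(ds), c(
    vapply(c("PatientName", "PatientID", "PatientBirthDate", "PatientAddress",
             "PatientTelephoneNumbers", "OtherPatientIDs", "InstitutionName",
             "OperatorsName", "ReferringPhysicianName", "AccessionNumber"),
           dcm_tag, "")))
  patient_attributes <- lapply(stats::setNames(id_tags, id_tags),
                               function(t) ds[[t]]$value)

  structure(list(
    sop_instance_uid = sop,
    series_instance_uid = series,
    study_instance_uid = study,
    sop_class_uid = ds_get(ds, "SOPClassUID", NA_character_),
    series_description = ds_get(ds, "SeriesDescription", NA_character_),
    modality = ds_get(ds, "Modality", NA_character_),
    instance_number = as.integer(ds_get(ds, "InstanceNumber", NA_integer_)),
    image_position_patient = ds_get(ds, "ImagePositionPatient"),
    image_orientation_patient = iop,
    pixel_spacing = ps,
    rows = as.integer(ds_get(ds, "Rows", NA_integer_)),
    columns = as.integer(ds_get(ds, "Columns", NA_integer_)),
    slice_thickness = ds_get(ds, "SliceThickness"),
    rescale_slope = ds_get(ds, "RescaleSlope", 1),
    rescale_intercept = ds_get(ds, "RescaleIntercept", 0),
    pixel_payload = ds_get(ds, "PixelData"),
    patient_attributes = patient_attributes,
    dataset = ds
  ), class = "dicom_instance_record")
}

#' Read an instance record from a Part-10 file
#' @param path File path.
#' @return A `dicom_instance_record`.
#' @export
read_instance <- function(path) dicom_instance_record(dcm_read(path))

#' Write an instance record back to a Part-10 file
#' @param record A `dicom_instance_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_instance <- function(record, path) {
  stopifnot(inherits(record, "dicom_instance_record"))
  dcm_write(record$dataset, path)
}

#' @export
print.dicom_instance_record <- function(x, ...) {
  cat(sprintf("<dicom_instance_record %s #%s of series %s (%s, %dx%d)>\n",
              substr(x$sop_instance_uid, 1, 16), x$instance_number,
              substr(x$series_instance_uid, 1, 16), x$modality,
              x$rows, x$columns))
  invisible(x)
}

# recursively apply `fn(tag, element) -> element or NULL` to a dataset
.walk_dataset <- function(ds, fn) {
  out <- list()
  for (tag in names(ds)) {
    el <- fn(tag, ds[[tag]])
    if (is.null(el)) next
    if (identical(el$vr, "SQ")) {
      el$value <- lapply(el$value, .walk_dataset, fn = fn)
    }
    out[[tag]] <- el
  }
  structure(out, class = "dcm_dataset")
}

.is_private_tag <- function(tag) (strtoi(substr(tag, 1, 4), 16L) %% 2L) == 1L

#' De-identify one instance
#'
#' Applies an [anonymization_profile()]: removes and replaces identity tags
#' at every nesting level, strips private tags, coarsens dates (DA values
#' become YYYY0101), and remaps Study/Series/SOP/FrameOfReference UIDs
#' through the session [uid_map()]. Geometry tags and the pixel payload are
#' byte-identical in the output; the input record is not modified.
#'
#' @param record A `dicom_instance_record`.
#' @param profile An [anonymization_profile()].
#' @param map A [uid_map()]; updated in place.
#' @return A new, de-identified `dicom_instance_record`.
#' @export
anonymize_instance <- function(record, profile, map) {
  stopifnot(inherits(record, "dicom_instance_record"),
            inherits(profile, "anonymization_profile"),
            inherits(map, "uid_map"))
  remove <- profile$remove_tags
  replace <- profile$replace_tags
  ds <- .walk_dataset(record$dataset, function(tag, el) {
    if (tag %in% remove) return(NULL)
    if (profile$strip_private && .is_private_tag(tag)) return(NULL)
    if (!is.null(replace[[tag]])) {
      el$value <- replace[[tag]]
      return(el)
    }
    if (profile$coarsen_dates && identical(el$vr, "DA") &&
        length(el$value) == 1L && nchar(el$value) >= 4L) {
      el$value <- paste0(substr(el$value, 1, 4), "0101")
    }
    if (profile$remap_uids && tag %in% .IDENTITY_UID_TAGS) {
      el$value <- remap_uid(el$value, map)
    }
    el
  })
  # replacement tags absent from the input are added (e.g. the
  # PatientIdentityRemoved marker)
  for (tag in setdiff(names(replace), names(ds))) {
    ds[[tag]] <- list(vr = dcm_vr_of(tag), value = replace[[tag]])
  }
  class(ds) <- "dcm_dataset"
  dicom_instance_record(ds)
}
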