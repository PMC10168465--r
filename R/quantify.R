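# Volumetry from label voxel data and the DICOM SR measurement document.
# Volumes are binary voxel counts times voxel volume, reported in mL to one
# decimal (half away from zero), matching how the downstream report states
# them.

.round_tenth <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10

#' Per-segment volumetry of a label volume
#'
#' One result row per descriptor: `voxel_count` is the number of voxels
#' equal to the descriptor's label id, `voxel_volume_mm3` the product of the
#' three spacings, and `volume_ml = voxel_count * voxel_volume_mm3 / 1000`
#' rounded half-away-from-zero to 0.1 mL. A descriptor whose label is absent
#' yields a zero-count row, not an error.
#'
#' @param labels A [label_volume()].
#' @param descriptors List of [segment_descriptor()].
#' @return A tibble with columns `label_id`, `segment_label`, `voxel_count`,
#'   `voxel_volume_mm3`, `volume_mm3`, `volume_ml`.
#' @export
compute_volumes <- function(labels, descriptors) {
  stopifnot(inherits(labels, "label_volume"))
  descriptors <- .check_descriptors(descriptors)
  spacing <- labels$geometry$spacing
  if (any(spacing <= 0)) stop("geometry has non-positive spacing", call. = FALSE)
  voxel_mm3 <- prod(spacing)
  tab <- tabulate(labels$labels, nbins = max(vapply(descriptors, function(d) d$label_id, 1L)))
  rows <- lapply(descriptors, function(d) {
    count <- tab[d$label_id]
    mm3 <- count * voxel_mm3
    tibble::tibble(label_id = d$label_id,
                   segment_label = d$segment_label,
                   voxel_count = count,
                   voxel_volume_mm3 = voxel_mm3,
                   volume_mm3 = mm3,
                   volume_ml = .round_tenth(mm3 / 1000))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("volumetry_result", class(out))
  out
}

.sr_num_item <- function(label, value_ml) {
  mv <- ds_new()
  mv <- ds_set(mv, "NumericValue", value_ml)
  mv <- ds_set(mv, "MeasurementUnitsCodeSequence",
               list(dcm_code_item("ml", "UCUM", "milliliter")))
  num <- ds_new()
  num <- ds_set(num, "RelationshipType", "CONTAINS")
  num <- ds_set(num, "ValueType", "NUM")
  num <- ds_set(num, "ConceptNameCodeSequence",
                list(dcm_code_item("118565006", "SCT", "Volume")))
  num <- ds_set(num, "MeasuredValueSequence", list(mv))
  num
}

.sr_text_item <- function(concept, text) {
  it <- ds_new()
  it <- ds_set(it, "RelationshipType", "CONTAINS")
  it <- ds_set(it, "ValueType", "TEXT")
  it <- ds_set(it, "ConceptNameCodeSequence", list(concept))
  ds_set(it, "TextValue", text)
}

#' Build the DICOM SR measurement document
#'
#' A minimal measurement-report structure (one measurement group per
#' segment) rather than full TID 1500 conformance: each segment contributes
#' a coded "Volume" numeric item in UCUM millilitres, a tracking-label text
#' item, and a human-readable summary line `"<segment_label> volume: <v>
#' mL"`. The document lives in the source study (same study UID, fresh
#' series/instance UIDs) and references the SEG instance and the source
#' series as evidence.
#'
#' @param results A [compute_volumes()] tibble (>= 1 row), ordered by
#'   ascending `label_id`.
#' @param seg_reference Character 2-vector: (SOP class UID, SOP instance
#'   UID) of the SEG object the volumes were measured from.
#' @param source_study_uid Study UID shared with the (anonymized) images.
#' @param source_series_uid Series UID of the source images.
#' @return A `dcm_dataset` (Comprehensive SR).
#' @export
build_structured_report <- function(results, seg_reference,
                                    source_study_uid, source_series_uid) {
  if (is.null(results) || nrow(results) == 0L) {
    stop(errorCondition("empty volumetry results", class = c("ctqv_validation_error", "ctqv_error")))
  }
  if (length(seg_reference) != 2L || !all(vapply(seg_reference, is_valid_uid, TRUE))) {
    stop(errorCondition("seg_reference must be a (SOP class UID, SOP instance UID) pair",
                        class = c("ctqv_validation_error", "ctqv_error")))
  }
  .assert_uid(source_study_uid, "source_study_uid")
  .assert_uid(source_series_uid, "source_series_uid")
  results <- results[order(results$label_id), ]

  groups <- lapply(seq_len(nrow(results)), function(i) {
    row <- results[i, ]
    grp <- ds_new()
    grp <- ds_set(grp, "RelationshipType", "CONTAINS")
    grp <- ds_set(grp, "ValueType", "CONTAINER")
    grp <- ds_set(grp, "ContinuityOfContent", "SEPARATE")
    grp <- ds_set(grp, "ConceptNameCodeSequence",
                  list(dcm_code_item("125007", "DCM", "Measurement Group")))
    children <- list(
      .sr_text_item(dcm_code_item("112039", "DCM", "Tracking Identifier"), row$segment_label),
      .sr_num_item(row$segment_label, row$volume_ml),
      .sr_text_item(dcm_code_item("121071", "DCM", "Finding"),
                    sprintf("%s volume: %.1f mL", row$segment_label, row$volume_ml))
    )
    ds_set(grp, "ContentSequence", children)
  })

  seg_ref_item <- ds_new()
  seg_ref_item <- ds_set(seg_ref_item, "ReferencedSOPClassUID", seg_reference[1])
  seg_ref_item <- ds_set(seg_ref_item, "ReferencedSOPInstanceUID", seg_reference[2])
  ref_seg_series <- ds_new()
  ref_seg_series <- ds_set(ref_seg_series, "ReferencedSOPSequence", list(seg_ref_item))
  src_series <- ds_new()
  src_series <- ds_set(src_series, "SeriesInstanceUID", source_series_uid)
  evidence_study <- ds_new()
  evidence_study <- ds_set(evidence_study, "StudyInstanceUID", source_study_uid)
  evidence_study <- ds_set(evidence_study, "ReferencedSeriesSequence",
                           list(ref_seg_series, src_series))

  root <- ds_new()
  root <- ds_set(root, "ValueType", "CONTAINER")
  root <- ds_set(root, "ContinuityOfContent", "SEPARATE")
  root <- ds_set(root, "ConceptNameCodeSequence",
                 list(dcm_code_item("126000", "DCM", "Imaging Measurement Report")))
  root <- ds_set(root, "ContentSequence", groups)

  sr <- ds_new()
  sr <- ds_set(sr, "SpecificCharacterSet", "ISO_IR 100")
  sr <- ds_set(sr, "SOPClassUID", DCM_UID$comprehensive_sr)
  sr <- ds_set(sr, "SOPInstanceUID", new_uid())
  sr <- ds_set(sr, "Modality", "SR")
  sr <- ds_set(sr, "Manufacturer", "ctqv")
  sr <- ds_set(sr, "SeriesDescription", "Volumetry report")
  sr <- ds_set(sr, "StudyInstanceUID", source_study_uid)
  sr <- ds_set(sr, "SeriesInstanceUID", new_uid())
  sr <- ds_set(sr, "SeriesNumber", 301L)
  sr <- ds_set(sr, "InstanceNumber", 1L)
  sr <- ds_set(sr, "CompletionFlag", "COMPLETE")
  sr <- ds_set(sr, "VerificationFlag", "UNVERIFIED")
  sr <- ds_set(sr, "ContentLabel", "VOLUMETRY")
  sr <- ds_set(sr, "CurrentRequestedProcedureEvidenceSequence", list(evidence_study))
  # merge root container items into the top-level dataset (document root)
  for (tag in names(root)) sr[[tag]] <- root[[tag]]
  class(sr) <- "dcm_dataset"
  sr
}

#' Extract the volume measurements from an SR document
#'
#' The inverse view of [build_structured_report()], used to audit SR content.
#'
#' @param sr An SR `dcm_dataset`.
#' @return A tibble with `segment_label`, `volume_ml`, `summary`, plus the
#'   referenced SEG instance UID and study UID as attributes.
#' @export
sr_measurements <- function(sr) {
  stopifnot(inherits(sr, "dcm_dataset"))
  if (!identical(ds_get(sr, "SOPClassUID"), DCM_UID$comprehensive_sr)) {
    stop("not a Comprehensive SR object", call. = FALSE)
  }
  groups <- ds_get(sr, "ContentSequence", list())
  rows <- lapply(groups, function(grp) {
    children <- ds_get(grp, "ContentSequence", list())
    lab <- NA_character_; vol <- NA_real_; summary <- NA_character_
    for (ch in children) {
      vt <- ds_get(ch, "ValueType")
      concept <- ds_get(ch, "ConceptNameCodeSequence", list())
      cv <- if (length(concept)) ds_get(concept[[1]], "CodeValue") else ""
      if (identical(vt, "TEXT") && identical(cv, "112039")) lab <- ds_get(ch, "TextValue")
      if (identical(vt, "TEXT") && identical(cv, "121071")) summary <- ds_get(ch, "TextValue")
      if (identical(vt, "NUM")) {
        mv <- ds_get(ch, "MeasuredValueSequence", list())
        if (length(mv)) vol <- as.numeric(ds_get(mv[[1]], "NumericValue"))
      }
    }
    tibble::tibble(segment_label = lab, volume_ml = vol, summary = summary)
  })
  out <- do.call(rbind, rows)
  ev <- ds_get(sr, "CurrentRequestedProcedureEvidenceSequence", list())
  if (length(ev)) {
    attr(out, "study_uid") <- ds_get(ev[[1]], "StudyInstanceUID")
    series <- ds_get(ev[[1]], "ReferencedSeriesSequence", list())
    for (s in series) {
      sop <- ds_get(s, "ReferencedSOPSequence", list())
      if (length(sop)) attr(out, "seg_sop_instance_uid") <- ds_get(sop[[1]], "ReferencedSOPInstanceUID")
      uid <- ds_get(s, "SeriesInstanceUID")
      if (!is.null(uid)) attr(out, "source_series_uid") <- uid
    }
  }
  out
}
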