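# DICOM Segmentation (SEG) object encoding and decoding. Binary
# segmentations only: one bit per voxel, one segment per descriptor, and
# frames emitted only for slices that contain at least one voxel of the
# segment (plane positions make the reconstruction unambiguous).

#' Convert an 8-bit sRGB display color to DICOM-scaled CIELab
#'
#' sRGB transfer function and D65 illuminant; the PCS values are scaled to
#' the 16-bit ranges the standard uses for Recommended Display CIELab Value
#' (L in 0..100 -> 0..65535; a, b in -128..127 -> 0..65535).
#'
#' @param rgb Integer 3-vector, 0..255.
#' @return Integer 3-vector of scaled CIELab values.
#' @export
rgb_to_cielab_uint16 <- function(rgb) {
  lab <- grDevices::convertColor(matrix(rgb / 255, nrow = 1), from = "sRGB", to = "Lab")
  as.integer(round(c(lab[1] * 65535 / 100,
                     (lab[2] + 128) * 65535 / 255,
                     (lab[3] + 128) * 65535 / 255)))
}

#' Convert DICOM-scaled CIELab back to 8-bit sRGB
#' @param lab16 Integer 3-vector of scaled CIELab values.
#' @return Integer 3-vector, 0..255.
#' @export
cielab_uint16_to_rgb <- function(lab16) {
  lab <- c(lab16[1] * 100 / 65535,
           lab16[2] * 255 / 65535 - 128,
           lab16[3] * 255 / 65535 - 128)
  srgb <- grDevices::convertColor(matrix(lab, nrow = 1), from = "Lab", to = "sRGB")
  as.integer(pmin(pmax(round(srgb * 255), 0), 255))
}

.descriptor_to_segment_item <- function(d) {
  item <- ds_new()
  item <- ds_set(item, "SegmentNumber", d$label_id)
  item <- ds_set(item, "SegmentLabel", d$segment_label)
  item <- ds_set(item, "SegmentAlgorithmType", d$algorithm_type)
  item <- ds_set(item, "SegmentAlgorithmName", d$algorithm_name)
  item <- ds_set(item, "SegmentedPropertyCategoryCodeSequence",
                 list(dcm_code_item(d$category_code[1], d$category_code[2], d$category_code[3])))
  item <- ds_set(item, "SegmentedPropertyTypeCodeSequence",
                 list(dcm_code_item(d$type_code[1], d$type_code[2], d$type_code[3])))
  ds_set(item, "RecommendedDisplayCIELabValue", rgb_to_cielab_uint16(d$display_color_rgb))
}

.segment_item_to_descriptor <- function(item) {
  cat_seq <- ds_get(item, "SegmentedPropertyCategoryCodeSequence", list())
  typ_seq <- ds_get(item, "SegmentedPropertyTypeCodeSequence", list())
  lab16 <- ds_get(item, "RecommendedDisplayCIELabValue")
  segment_descriptor(
    label_id = ds_get(item, "SegmentNumber"),
    segment_label = ds_get(item, "SegmentLabel", "segment"),
    category_code = if (length(cat_seq)) .code_from_item(cat_seq[[1]]) else c("UNK", "UNK", "unknown"),
    type_code = if (length(typ_seq)) .code_from_item(typ_seq[[1]]) else c("UNK", "UNK", "unknown"),
    display_color_rgb = if (!is.null(lab16)) cielab_uint16_to_rgb(lab16) else c(255L, 0L, 0L),
    algorithm_type = ds_get(item, "SegmentAlgorithmType", "AUTOMATIC"),
    algorithm_name = ds_get(item, "SegmentAlgorithmName", "unknown")
  )
}

#' Encode a label volume as a DICOM SEG object
#'
#' Produces a binary segmentation co-registered to the source series: study
#' and frame-of-reference UIDs are taken from the source instances (already
#' anonymized when the router hands them over), the SEG series is a fresh
#' UID under the same study, and each frame carries its plane position plus
#' a derivation reference to the source slice's SOP instance. Only slices
#' containing at least one voxel of a segment are emitted as frames for that
#' segment. An all-background label volume yields no SEG (a frameless SEG is
#' non-conformant): an `empty_segmentation` marker is returned instead.
#'
#' @param label_volume A [label_volume()] on the source series grid.
#' @param descriptors List of [segment_descriptor()], covering every label
#'   present.
#' @param source Sorted list of [dicom_instance_record()] (the series the
#'   mask was computed from).
#' @return A `dcm_dataset` (the SEG object), or an object of class
#'   `empty_segmentation` when the mask has no foreground.
#' @export
encode_seg <- function(label_volume, descriptors, source) {
  stopifnot(inherits(label_volume, "label_volume"))
  descriptors <- .check_descriptors(descriptors)
  ids <- vapply(descriptors, function(d) d$label_id, 1L)
  missing_desc <- setdiff(label_volume$label_ids_present, ids)
  if (length(missing_desc)) {
    stop(errorCondition(paste0("no segment descriptor for label(s) ",
                               paste(missing_desc, collapse = ", ")),
                        class = c("ctqv_semantics_error", "ctqv_error")))
  }
  src_geom <- series_geometry(source)
  if (!geom_equal(label_volume$geometry, src_geom, tol = 1e-3)) {
    .geometry_error("label volume geometry does not match the source series")
  }
  if (!length(label_volume$label_ids_present)) {
    return(structure(list(source_series_uid = source[[1]]$series_instance_uid),
                     class = "empty_segmentation"))
  }

  geom <- label_volume$geometry
  labels <- label_volume$labels
  rows <- geom$shape[1]; cols <- geom$shape[2]; n_slices <- geom$shape[3]
  first <- source[[1]]

  frames <- list()      # per frame: segment number, slice index
  for (d in descriptors) {
    present <- which(vapply(seq_len(n_slices),
                            function(k) any(labels[, , k] == d$label_id), TRUE))
    for (k in present) frames[[length(frames) + 1L]] <- c(d$label_id, k)
  }
  n_frames <- length(frames)

  bits <- logical(0)
  per_frame <- vector("list", n_frames)
  all_bits <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    seg_no <- frames[[i]][1]; k <- frames[[i]][2]
    plane <- labels[, , k] == seg_no
    all_bits[[i]] <- as.vector(t(plane))          # row-major
    ipp <- geom$origin + (k - 1) * geom$spacing[3] * geom$slice_direction

    fc <- ds_new(); fc <- ds_set(fc, "DimensionIndexValues", c(seg_no, k))
    pp <- ds_new(); pp <- ds_set(pp, "ImagePositionPatient", ipp)
    si <- ds_new()
    si <- ds_set(si, "ReferencedSOPClassUID", source[[k]]$sop_class_uid)
    si <- ds_set(si, "ReferencedSOPInstanceUID", source[[k]]$sop_instance_uid)
    dv <- ds_new(); dv <- ds_set(dv, "SourceImageSequence", list(si))
    sg <- ds_new(); sg <- ds_set(sg, "ReferencedSegmentNumber", seg_no)
    item <- ds_new()
    item <- ds_set(item, "FrameContentSequence", list(fc))
    item <- ds_set(item, "PlanePositionSequence", list(pp))
    item <- ds_set(item, "DerivationImageSequence", list(dv))
    item <- ds_set(item, "SegmentIdentificationSequence", list(sg))
    per_frame[[i]] <- item
  }
  pixel_data <- pack_bits(unlist(all_bits))

  pm <- ds_new()
  pm <- ds_set(pm, "PixelSpacing", geom$spacing[1:2])
  pm <- ds_set(pm, "SliceThickness", geom$spacing[3])
  pm <- ds_set(pm, "SpacingBetweenSlices", geom$spacing[3])
  po <- ds_new()
  po <- ds_set(po, "ImageOrientationPatient", c(geom$row_direction, geom$column_direction))
  shared <- ds_new()
  shared <- ds_set(shared, "PixelMeasuresSequence", list(pm))
  shared <- ds_set(shared, "PlaneOrientationSequence", list(po))

  ref_instances <- lapply(source, function(r) {
    it <- ds_new()
    it <- ds_set(it, "ReferencedSOPClassUID", r$sop_class_uid)
    ds_set(it, "ReferencedSOPInstanceUID", r$sop_instance_uid)
  })
  ref_series <- ds_new()
  ref_series <- ds_set(ref_series, "SeriesInstanceUID", first$series_instance_uid)
  ref_series <- ds_set(ref_series, "ReferencedInstanceSequence", ref_instances)

  seg <- ds_new()
  seg <- ds_set(seg, "SpecificCharacterSet", "ISO_IR 100")
  seg <- ds_set(seg, "ImageType", c("DERIVED", "PRIMARY"))
  seg <- ds_set(seg, "SOPClassUID", DCM_UID$segmentation_storage)
  seg <- ds_set(seg, "SOPInstanceUID", new_uid())
  seg <- ds_set(seg, "Modality", "SEG")
  seg <- ds_set(seg, "Manufacturer", "ctqv")
  seg <- ds_set(seg, "SeriesDescription", "Segmentation")
  seg <- ds_set(seg, "StudyInstanceUID", first$study_instance_uid)
  seg <- ds_set(seg, "SeriesInstanceUID", new_uid())
  seg <- ds_set(seg, "SeriesNumber", 300L)
  seg <- ds_set(seg, "InstanceNumber", 1L)
  if (ds_has(first$dataset, "FrameOfReferenceUID")) {
    seg <- ds_set(seg, "FrameOfReferenceUID", ds_get(first$dataset, "FrameOfReferenceUID"))
  }
  if (ds_has(first$dataset, "StudyDate")) {
    seg <- ds_set(seg, "StudyDate", ds_get(first$dataset, "StudyDate"))
    seg <- ds_set(seg, "ContentDate", ds_get(first$dataset, "StudyDate"))
  }
  seg <- ds_set(seg, "ContentLabel", "SEGMENTATION")
  seg <- ds_set(seg, "ContentDescription", "ctqv segmentation")
  seg <- ds_set(seg, "ContentCreatorName", "ctqv")
  seg <- ds_set(seg, "SamplesPerPixel", 1L)
  seg <- ds_set(seg, "PhotometricInterpretation", "MONOCHROME2")
  seg <- ds_set(seg, "NumberOfFrames", n_frames)
  seg <- ds_set(seg, "Rows", rows)
  seg <- ds_set(seg, "Columns", cols)
  seg <- ds_set(seg, "BitsAllocated", 1L)
  seg <- ds_set(seg, "BitsStored", 1L)
  seg <- ds_set(seg, "HighBit", 0L)
  seg <- ds_set(seg, "PixelRepresentation", 0L)
  seg <- ds_set(seg, "SegmentationType", "BINARY")
  seg <- ds_set(seg, "SegmentSequence", lapply(descriptors, .descriptor_to_segment_item))
  seg <- ds_set(seg, "SharedFunctionalGroupsSequence", list(shared))
  seg <- ds_set(seg, "PerFrameFunctionalGroupsSequence", per_frame)
  seg <- ds_set(seg, "ReferencedSeriesSequence", list(ref_series))
  seg <- ds_set(seg, "PixelData", pixel_data)
  seg
}

#' Decode a DICOM SEG object into a label volume
#'
#' Frames are placed at their plane positions on the reconstruction grid.
#' When `geometry` (the source series grid) is supplied, frames are placed
#' onto it; otherwise a minimal grid spanning the occupied planes is
#' inferred from the frame geometry. Voxels covered by no frame are 0. Where
#' two segments claim the same voxel, the higher segment number wins and a
#' warning is raised.
#'
#' @param seg A SEG `dcm_dataset` (from [encode_seg()] or [dcm_read()]).
#' @param geometry Optional [volume_geometry()] of the source series.
#' @return A list: `labels` ([label_volume()]), `descriptors` (list of
#'   [segment_descriptor()]), `referenced_series_uid`.
#' @export
decode_seg <- function(seg, geometry = NULL) {
  stopifnot(inherits(seg, "dcm_dataset"))
  if (!identical(ds_get(seg, "SOPClassUID"), DCM_UID$segmentation_storage)) {
    stop(errorCondition("not a Segmentation Storage object",
                        class = c("ctqv_not_seg_error", "ctqv_error")))
  }
  if (!identical(toupper(ds_get(seg, "SegmentationType", "")), "BINARY")) {
    stop(errorCondition("only BINARY segmentations are supported (FRACTIONAL is not)",
                        class = c("ctqv_unsupported_variant", "ctqv_error")))
  }
  rows <- as.integer(ds_get(seg, "Rows")); cols <- as.integer(ds_get(seg, "Columns"))
  n_frames <- as.integer(ds_get(seg, "NumberOfFrames"))
  shared <- ds_get(seg, "SharedFunctionalGroupsSequence", list())[[1]]
  po <- ds_get(shared, "PlaneOrientationSequence", list())
  iop <- ds_get(po[[1]], "ImageOrientationPatient")
  pm <- ds_get(shared, "PixelMeasuresSequence", list())
  ps <- ds_get(pm[[1]], "PixelSpacing")
  thick <- ds_get(pm[[1]], "SpacingBetweenSlices",
                  ds_get(pm[[1]], "SliceThickness", 1))

  per_frame <- ds_get(seg, "PerFrameFunctionalGroupsSequence", list())
  if (length(per_frame) != n_frames || n_frames == 0L) {
    stop(errorCondition("SEG has no decodable frames",
                        class = c("ctqv_no_frames_error", "ctqv_error")))
  }
  positions <- t(vapply(per_frame, function(f) {
    ds_get(ds_get(f, "PlanePositionSequence", list())[[1]], "ImagePositionPatient")
  }, numeric(3)))
  seg_numbers <- vapply(per_frame, function(f) {
    as.integer(ds_get(ds_get(f, "SegmentIdentificationSequence", list())[[1]],
                      "ReferencedSegmentNumber"))
  }, 1L)

  row_dir <- iop[1:3]; col_dir <- iop[4:6]
  normal <- .cross3(row_dir, col_dir)
  proj <- as.vector(positions %*% normal)

  if (is.null(geometry)) {
    uproj <- sort(unique(round(proj, 6)))
    if (length(uproj) > 1L) {
      gaps <- diff(uproj)
      spacing3 <- min(gaps)
      steps <- gaps / spacing3
      if (max(abs(steps - round(steps))) > 1e-3) {
        .geometry_error("frame plane positions are not on a regular grid")
      }
    } else {
      spacing3 <- as.numeric(thick)
    }
    n_slices <- as.integer(round((max(uproj) - min(uproj)) / spacing3)) + 1L
    base_idx <- which.min(proj)
    origin <- positions[base_idx, ]
    geometry <- volume_geometry(origin = origin, row_direction = row_dir,
                                column_direction = col_dir,
                                spacing = c(ps[1], ps[2], spacing3),
                                shape = c(rows, cols, n_slices))
  } else {
    if (!identical(geometry$shape[1:2], as.integer(c(rows, cols)))) {
      .geometry_error("SEG frame size does not match the supplied geometry")
    }
  }
  if (max(abs(iop[1:3] - geometry$row_direction)) > 1e-3 ||
      max(abs(iop[4:6] - geometry$column_direction)) > 1e-3) {
    .geometry_error("frames with inconsistent orientation")
  }

  origin_proj <- sum(geometry$origin * normal)
  slice_idx <- round((proj - origin_proj) / geometry$spacing[3]) + 1L
  if (any(slice_idx < 1L | slice_idx > geometry$shape[3])) {
    .geometry_error("frame plane position outside the reconstruction grid")
  }

  bits <- unpack_bits(ds_get(seg, "PixelData"), n_frames * rows * cols)
  labels <- array(0L, dim = geometry$shape)
  overlap <- FALSE
  ord <- order(seg_numbers)       # ascending: higher segment number wins
  for (i in ord) {
    frame_bits <- bits[((i - 1) * rows * cols + 1):(i * rows * cols)]
    plane <- t(matrix(frame_bits, nrow = cols))
    k <- slice_idx[i]
    existing <- labels[, , k]
    if (any(existing[plane] != 0L & existing[plane] != seg_numbers[i])) overlap <- TRUE
    existing[plane] <- seg_numbers[i]
    labels[, , k] <- existing
  }
  if (overlap) {
    warning("overlapping segments: voxels claimed by multiple segments resolved to the highest segment number",
            call. = FALSE)
  }

  descriptors <- lapply(ds_get(seg, "SegmentSequence", list()), .segment_item_to_descriptor)
  ref <- ds_get(seg, "ReferencedSeriesSequence", list())
  ref_uid <- if (length(ref)) ds_get(ref[[1]], "SeriesInstanceUID", NA_character_) else NA_character_

  list(labels = label_volume(labels, geometry),
       descriptors = descriptors,
       referenced_series_uid = ref_uid)
}
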