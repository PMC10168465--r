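# Shared fixtures: all built in code at test time.

# A minimal in-memory CT dataset (one slice) for router/codec tests.
tiny_ct_dataset <- function(series_uid, sop_uid, z = 0, study_uid = "1.2.840.99.1",
                            instance_number = 1L, rows = 8L, cols = 8L,
                            series_description = "ABD PV PORTAL 3MM",
                            pixel_spacing = c(1, 1), iop = c(1, 0, 0, 0, 1, 0),
                            ipp = NULL, stored_value = 1044L,
                            patient_name = "DOE^JANE") {
  ds <- ds_new()
  ds <- ds_set(ds, "SOPClassUID", "1.2.840.10008.5.1.4.1.1.2")
  ds <- ds_set(ds, "SOPInstanceUID", sop_uid)
  ds <- ds_set(ds, "StudyInstanceUID", study_uid)
  ds <- ds_set(ds, "SeriesInstanceUID", series_uid)
  ds <- ds_set(ds, "FrameOfReferenceUID", paste0(study_uid, ".9"))
  ds <- ds_set(ds, "Modality", "CT")
  ds <- ds_set(ds, "SeriesDescription", series_description)
  ds <- ds_set(ds, "PatientName", patient_name)
  ds <- ds_set(ds, "PatientID", "TINY-1")
  ds <- ds_set(ds, "StudyDate", "20200315")
  ds <- ds_set(ds, "InstanceNumber", instance_number)
  ds <- ds_set(ds, "ImagePositionPatient", if (is.null(ipp)) c(0, 0, z) else ipp)
  ds <- ds_set(ds, "ImageOrientationPatient", iop)
  ds <- ds_set(ds, "PixelSpacing", pixel_spacing)
  ds <- ds_set(ds, "SliceThickness", 3)
  ds <- ds_set(ds, "Rows", rows)
  ds <- ds_set(ds, "Columns", cols)
  ds <- ds_set(ds, "SamplesPerPixel", 1L)
  ds <- ds_set(ds, "PhotometricInterpretation", "MONOCHROME2")
  ds <- ds_set(ds, "BitsAllocated", 16L)
  ds <- ds_set(ds, "BitsStored", 16L)
  ds <- ds_set(ds, "HighBit", 15L)
  ds <- ds_set(ds, "PixelRepresentation", 0L)
  ds <- ds_set(ds, "RescaleIntercept", -1024)
  ds <- ds_set(ds, "RescaleSlope", 1)
  ds <- ds_set(ds, "PixelData",
               writeBin(rep(as.integer(stored_value), rows * cols), raw(),
                        size = 2, endian = "little"))
  ds
}

tiny_ct_record <- function(...) dicom_instance_record(tiny_ct_dataset(...))

# A small lesion phantom used across tests.
small_lesion_spec <- function(shape = c(48L, 48L, 16L), spacing = c(1, 1), slice = 3,
                              semi_axes = NULL, hu = 60, seed = 1L,
                              noise_sd = 0) {
  extents <- c(shape[2] * spacing[2], shape[1] * spacing[1], shape[3] * slice)
  if (is.null(semi_axes)) semi_axes <- extents * c(0.25, 0.21, 0.29)
  center <- c((shape[2] - 1) * spacing[2] / 2,
              (shape[1] - 1) * spacing[1] / 2,
              (shape[3] - 1) * slice / 2)
  phantom_spec(shape = shape, pixel_spacing = spacing, slice_spacing = slice,
               lesions = list(list(kind = "ellipsoid", center = center,
                                   semi_axes = semi_axes, hu = hu, label_id = 1L)),
               noise_sd = noise_sd, seed = seed)
}

# Write a pipeline config YAML pointing at a fresh segment-attributes file.
write_test_config <- function(dir = tempfile("cfg_"),
                              patterns = "PV",
                              timeout_seconds = 30,
                              extra = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  attrs <- file.path(dir, "segment_attributes.json")
  write_segment_attributes(
    list(segment_descriptor(1L, "pelvic hematoma"),
         segment_descriptor(2L, "second lesion", display_color_rgb = c(38L, 38L, 216L))),
    attrs)
  path <- file.path(dir, "config.yaml")
  writeLines(sprintf('
router:    {ae_title: CTQV_ROUTER, host: 127.0.0.1, port: 11112}
archive:   {ae_title: ARCHIVE, host: 127.0.0.1, port: 11113}
processor: {ae_title: DLHOST, host: 127.0.0.1, port: 11114}
series_filter: {mode: substring, patterns: ["%s"], match_field: series_description}
timeout_seconds: %s
backend: {kind: threshold_stub, hu_low: 40, hu_high: 80}
segment_attributes_path: %s
%s', paste(patterns, collapse = '", "'), format(timeout_seconds), attrs, extra), path)
  path
}

# Independent 26-connectivity component labelling by breadth-first search,
# used as the oracle against the package's graph-based implementation.
bfs_components_26 <- function(mask) {
  dims <- dim(mask)
  out <- array(0L, dim = dims)
  comp <- 0L
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, ]
  for (start in which(mask & out == 0L)) {
    if (out[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    out[start] <- comp
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      vi <- arrayInd(v, dims)
      for (s in seq_len(nrow(shifts))) {
        nb <- vi + shifts[s, ]
        if (any(nb < 1L) || any(nb > dims)) next
        lin <- nb[1] + (nb[2] - 1L) * dims[1] + (nb[3] - 1L) * dims[1] * dims[2]
        if (mask[lin] && out[lin] == 0L) {
          out[lin] <- comp
          queue <- c(queue, lin)
        }
      }
    }
  }
  out
}

# Random sparse label volume on a small grid (for SEG round-trip tests).
random_label_volume <- function(shape = c(12L, 12L, 8L), n_labels = 2L,
                                density = 0.05, spacing = c(1, 1.2, 2.5)) {
  labels <- array(0L, dim = shape)
  n <- prod(shape)
  for (id in seq_len(n_labels)) {
    k <- max(1L, rbinom(1, n, density))
    labels[sample.int(n, k)] <- id
  }
  geom <- volume_geometry(origin = runif(3, -50, 50),
                          row_direction = c(1, 0, 0),
                          column_direction = c(0, 1, 0),
                          spacing = spacing, shape = shape)
  label_volume(labels, geom)
}

# A synthetic sorted source series matching a geometry (for encode_seg).
source_series_for_geometry <- function(geom, study_uid = "1.2.840.99.77") {
  series_uid <- paste0(study_uid, ".2")
  lapply(seq_len(geom$shape[3]), function(k) {
    ipp <- geom$origin + (k - 1) * geom$spacing[3] * geom$slice_direction
    tiny_ct_record(series_uid = series_uid,
                   sop_uid = paste0(series_uid, ".", k),
                   study_uid = study_uid,
                   instance_number = k,
                   rows = geom$shape[1], cols = geom$shape[2],
                   pixel_spacing = geom$spacing[1:2],
                   iop = c(geom$row_direction, geom$column_direction),
                   ipp = ipp)
  })
}

# Random orthonormal orientation (row, column direction pair).
random_orientation <- function() {
  m <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(m) < 0) m[, 3] <- -m[, 3]
  list(row = m[, 1], col = m[, 2])
}
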