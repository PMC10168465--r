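test_that("encode/decode round-trips label voxels exactly on the source grid", {
  set.seed(61)
  for (i in 1:10) {
    lv <- random_label_volume(shape = c(10L, 12L, 6L), n_labels = 2L)
    src <- source_series_for_geometry(lv$geometry)
    descs <- list(segment_descriptor(1L, "lesion one"),
                  segment_descriptor(2L, "lesion two", display_color_rgb = c(0L, 128L, 255L)))
    seg <- encode_seg(lv, descs[seq_along(lv$label_ids_present)], src)
    if (inherits(seg, "empty_segmentation")) next
    dec <- decode_seg(seg, geometry = lv$geometry)
    expect_identical(dec$labels$labels, lv$labels)
    expect_identical(dec$labels$label_ids_present, lv$label_ids_present)
  }
})

test_that("SEG linkage: study kept, new series, source series referenced", {
  set.seed(62)
  lv <- random_label_volume()
  src <- source_series_for_geometry(lv$geometry, study_uid = "1.2.840.99.555")
  descs <- lapply(lv$label_ids_present, function(id) segment_descriptor(id, paste0("seg", id)))
  seg <- encode_seg(lv, descs, src)
  expect_identical(ds_get(seg, "StudyInstanceUID"), "1.2.840.99.555")
  expect_false(identical(ds_get(seg, "SeriesInstanceUID"), src[[1]]$series_instance_uid))
  expect_identical(ds_get(seg, "FrameOfReferenceUID"),
                   ds_get(src[[1]]$dataset, "FrameOfReferenceUID"))
  dec <- decode_seg(seg)
  expect_identical(dec$referenced_series_uid, src[[1]]$series_instance_uid)
})

test_that("frame economy: frame count equals the sum of nonzero-slice counts per segment", {
  set.seed(63)
  for (i in 1:10) {
    lv <- random_label_volume(shape = c(8L, 8L, 10L), n_labels = 3L, density = 0.02)
    if (!length(lv$label_ids_present)) next
    src <- source_series_for_geometry(lv$geometry)
    descs <- lapply(lv$label_ids_present, function(id) segment_descriptor(id, paste0("seg", id)))
    seg <- encode_seg(lv, descs, src)
    # brute-force oracle: count nonzero slices per segment
    expected <- sum(vapply(lv$label_ids_present, function(id) {
      sum(vapply(seq_len(dim(lv$labels)[3]), function(k) any(lv$labels[, , k] == id), TRUE))
    }, 0L))
    expect_identical(as.integer(ds_get(seg, "NumberOfFrames")), expected)
    expect_length(ds_get(seg, "PerFrameFunctionalGroupsSequence"), expected)
  }
})

test_that("a label occupying slices 10-14 of 100 yields exactly 5 frames", {
  set.seed(64)
  geom <- volume_geometry(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 3), c(8L, 8L, 100L))
  labels <- array(0L, dim = c(8, 8, 100))
  labels[4:6, 4:6, 10:14] <- 1L
  lv <- label_volume(labels, geom)
  src <- source_series_for_geometry(geom)
  seg <- encode_seg(lv, list(segment_descriptor(1L, "lesion")), src)
  expect_identical(as.integer(ds_get(seg, "NumberOfFrames")), 5L)
  # frames carry derivation references to the correct source slices
  pf <- ds_get(seg, "PerFrameFunctionalGroupsSequence")
  ref <- vapply(pf, function(f) {
    ds_get(ds_get(ds_get(f, "DerivationImageSequence")[[1]],
                  "SourceImageSequence")[[1]], "ReferencedSOPInstanceUID")
  }, "")
  expect_identical(ref, vapply(src[10:14], function(r) r$sop_instance_uid, ""))
  dec <- decode_seg(seg, geometry = geom)
  expect_identical(dec$labels$labels, labels)
})

test_that("decoding without the source grid still recovers every labelled voxel", {
  set.seed(65)
  geom <- volume_geometry(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 3), c(8L, 8L, 20L))
  labels <- array(0L, dim = c(8, 8, 20))
  labels[2:4, 2:4, 5:7] <- 1L
  labels[5:6, 5:6, 12:13] <- 2L
  lv <- label_volume(labels, geom)
  src <- source_series_for_geometry(geom)
  seg <- encode_seg(lv, list(segment_descriptor(1L, "a"), segment_descriptor(2L, "b")), src)
  dec <- decode_seg(seg)
  expect_identical(dec$labels$label_ids_present, c(1L, 2L))
  expect_identical(tabulate(dec$labels$labels, 2), tabulate(labels, 2))
})

test_that("overlapping segments resolve to the highest segment number with a warning", {
  geom <- volume_geometry(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 3), c(6L, 6L, 3L))
  src <- source_series_for_geometry(geom)
  # construct a two-segment SEG sharing one voxel by concatenating two
  # single-label encodings' frames is equivalent to encoding overlapping
  # masks; build it by patching the per-frame bits directly
  l1 <- array(0L, dim = c(6, 6, 3)); l1[2:3, 2:3, 2] <- 1L
  l2 <- array(0L, dim = c(6, 6, 3)); l2[3:4, 3:4, 2] <- 2L   # shares voxel (3,3,2)
  seg1 <- encode_seg(label_volume(l1, geom), list(segment_descriptor(1L, "a")), src)
  seg2 <- encode_seg(label_volume(l2, geom), list(segment_descriptor(2L, "b")), src)
  merged <- seg1
  merged <- ds_set(merged, "SegmentSequence",
                   c(ds_get(seg1, "SegmentSequence"), ds_get(seg2, "SegmentSequence")))
  merged <- ds_set(merged, "PerFrameFunctionalGroupsSequence",
                   c(ds_get(seg1, "PerFrameFunctionalGroupsSequence"),
                     ds_get(seg2, "PerFrameFunctionalGroupsSequence")))
  merged <- ds_set(merged, "NumberOfFrames", 2L)
  bits1 <- unpack_bits(ds_get(seg1, "PixelData"), 36)
  bits2 <- unpack_bits(ds_get(seg2, "PixelData"), 36)
  merged <- ds_set(merged, "PixelData", pack_bits(c(bits1, bits2)))
  expect_warning(dec <- decode_seg(merged, geometry = geom), "highest segment number")
  expect_identical(dec$labels$labels[3, 3, 2], 2L)
  expect_identical(dec$labels$labels[2, 2, 2], 1L)
  expect_identical(dec$labels$labels[4, 4, 2], 2L)
})

test_that("labels without descriptors and empty masks are handled as specified", {
  geom <- volume_geometry(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 3), c(6L, 6L, 3L))
  src <- source_series_for_geometry(geom)
  labels <- array(0L, dim = c(6, 6, 3)); labels[2, 2, 1] <- 2L
  expect_error(encode_seg(label_volume(labels, geom), list(segment_descriptor(1L, "a")), src),
               class = "ctqv_semantics_error")
  empty <- label_volume(array(0L, dim = c(6, 6, 3)), geom)
  marker <- encode_seg(empty, list(segment_descriptor(1L, "a")), src)
  expect_s3_class(marker, "empty_segmentation")
})

test_that("fractional segmentations are rejected as unsupported", {
  set.seed(66)
  lv <- random_label_volume()
  src <- source_series_for_geometry(lv$geometry)
  descs <- lapply(lv$label_ids_present, function(id) segment_descriptor(id, "x"))
  seg <- encode_seg(lv, descs, src)
  seg <- ds_set(seg, "SegmentationType", "FRACTIONAL")
  expect_error(decode_seg(seg), class = "ctqv_unsupported_variant")
})

test_that("display colors survive the RGB -> scaled CIELab -> RGB conversion", {
  for (rgb in list(c(216L, 38L, 38L), c(0L, 255L, 0L), c(12L, 90L, 200L), c(255L, 255L, 255L))) {
    lab16 <- rgb_to_cielab_uint16(rgb)
    expect_true(all(lab16 >= 0L & lab16 <= 65535L))
    back <- cielab_uint16_to_rgb(lab16)
    expect_true(all(abs(back - rgb) <= 1L))
  }
})

test_that("segment descriptors round-trip through the SEG segment sequence", {
  set.seed(67)
  geom <- volume_geometry(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 3), c(6L, 6L, 3L))
  labels <- array(0L, dim = c(6, 6, 3)); labels[2:3, 2:3, 2] <- 1L
  src <- source_series_for_geometry(geom)
  d <- segment_descriptor(1L, "pelvic hematoma",
                          category_code = c("M-01000", "SRT", "Morphologically Altered Structure"),
                          type_code = c("M-35000", "SRT", "Hemorrhage"),
                          display_color_rgb = c(216L, 38L, 38L),
                          algorithm_type = "AUTOMATIC", algorithm_name = "nnU-net")
  seg <- encode_seg(label_volume(labels, geom), list(d), src)
  dec <- decode_seg(seg, geometry = geom)
  got <- dec$descriptors[[1]]
  expect_identical(got$label_id, 1L)
  expect_identical(got$segment_label, "pelvic hematoma")
  expect_identical(got$type_code, d$type_code)
  expect_identical(got$algorithm_name, "nnU-net")
  expect_true(all(abs(got$display_color_rgb - d$display_color_rgb) <= 1L))
})
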