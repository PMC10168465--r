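unit_geom <- function(shape, spacing = c(1, 1, 1)) {
  volume_geometry(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), spacing, shape)
}

test_that("voxel counting volumetry matches forced arithmetic", {
  # empty mask
  empty <- label_volume(array(0L, dim = c(10, 10, 10)), unit_geom(c(10L, 10L, 10L)))
  r <- compute_volumes(empty, list(segment_descriptor(1L, "lesion")))
  expect_identical(r$voxel_count, 0L)
  expect_identical(r$volume_ml, 0)

  # 1000 voxels at 1 mm isotropic = 1000 mm^3 = 1.0 mL
  labels <- array(0L, dim = c(10, 10, 10)); labels[1:10, 1:10, 1:10] <- 1L
  r <- compute_volumes(label_volume(labels, unit_geom(c(10L, 10L, 10L))),
                       list(segment_descriptor(1L, "cube")))
  expect_identical(r$voxel_count, 1000L)
  expect_identical(r$volume_ml, 1.0)

  # 20x20x10 cuboid at 0.8x0.8x3.0 mm: 4000 x 1.92 mm^3 = 7680 mm^3 -> 7.7 mL
  labels <- array(0L, dim = c(24, 24, 12)); labels[1:20, 1:20, 1:10] <- 1L
  r <- compute_volumes(label_volume(labels, unit_geom(c(24L, 24L, 12L), c(0.8, 0.8, 3.0))),
                       list(segment_descriptor(1L, "cuboid")))
  expect_identical(r$voxel_count, 4000L)
  expect_equal(r$volume_mm3, 7680)
  expect_identical(r$volume_ml, 7.7)
})

test_that("a digitized 10 mm sphere matches the exhaustive center-inclusion oracle", {
  set.seed(71)
  spec <- phantom_spec(shape = c(30L, 30L, 30L), pixel_spacing = c(1, 1), slice_spacing = 1,
                       lesions = list(list(kind = "ellipsoid", center = c(14.5, 14.5, 14.5),
                                           semi_axes = c(10, 10, 10), hu = 60, label_id = 1L)))
  truth <- phantom_truth(spec)
  # independent oracle: exhaustive voxel-center test
  count <- 0L
  for (r in 1:30) for (cc in 1:30) for (k in 1:30) {
    x <- cc - 1; y <- r - 1; z <- k - 1
    if (((x - 14.5) / 10)^2 + ((y - 14.5) / 10)^2 + ((z - 14.5) / 10)^2 <= 1) count <- count + 1L
  }
  res <- compute_volumes(truth, list(segment_descriptor(1L, "sphere")))
  expect_identical(res$voxel_count, count)
  expect_identical(res$volume_ml, .round_tenth(count / 1000))
  analytic <- 4 / 3 * pi * 10^3 / 1000
  expect_lt(abs(res$volume_mm3 / 1000 - analytic) / analytic, 0.03)
})

test_that("volumes are additive over disjoint labels and covariant under scaling", {
  set.seed(72)
  labels <- array(0L, dim = c(16, 16, 8))
  labels[2:6, 2:6, 2:4] <- 1L
  labels[9:14, 9:13, 5:7] <- 2L
  lv <- label_volume(labels, unit_geom(c(16L, 16L, 8L), c(0.7, 1.1, 2.3)))
  descs <- list(segment_descriptor(1L, "a"), segment_descriptor(2L, "b"))
  r <- compute_volumes(lv, descs)
  union <- array(0L, dim = c(16, 16, 8)); union[labels > 0L] <- 1L
  r_union <- compute_volumes(label_volume(union, lv$geometry), list(segment_descriptor(1L, "u")))
  expect_equal(r_union$volume_mm3, sum(r$volume_mm3))

  doubled <- label_volume(labels, unit_geom(c(16L, 16L, 8L), 2 * c(0.7, 1.1, 2.3)))
  r2 <- compute_volumes(doubled, descs)
  expect_equal(r2$volume_mm3, 8 * r$volume_mm3)
})

test_that("rounding is half-away-from-zero to one decimal", {
  expect_identical(.round_tenth(0.05), 0.1)
  expect_identical(.round_tenth(0.44999), 0.4)
  expect_identical(.round_tenth(7.65), 7.7)
  expect_identical(.round_tenth(-0.05), -0.1)
  # a voxel count engineered to land exactly on a 0.05 mL tie
  labels <- array(0L, dim = c(10, 10, 5)); labels[seq_len(50)] <- 1L
  r <- compute_volumes(label_volume(labels, unit_geom(c(10L, 10L, 5L))),
                       list(segment_descriptor(1L, "tie")))
  expect_equal(r$volume_mm3, 50)
  expect_identical(r$volume_ml, 0.1)
})

test_that("a descriptor for an absent label yields a zero row, not an error", {
  labels <- array(0L, dim = c(6, 6, 2)); labels[1:2, 1:2, 1] <- 1L
  lv <- label_volume(labels, unit_geom(c(6L, 6L, 2L)))
  r <- compute_volumes(lv, list(segment_descriptor(1L, "present"),
                                segment_descriptor(5L, "absent")))
  expect_identical(r$voxel_count, c(4L, 0L))
  expect_identical(r$volume_ml[2], 0)
})

test_that("the SR carries coded volume measurements, summaries and linkage", {
  set.seed(73)
  labels <- array(0L, dim = c(40, 40, 25))
  labels[1:40, 1:40, 1:25] <- 1L   # 40000 voxels x 1 mm^3 = 40.0 mL
  lv <- label_volume(labels, unit_geom(c(40L, 40L, 25L)))
  r <- compute_volumes(lv, list(segment_descriptor(1L, "Spleen")))
  expect_identical(r$volume_ml, 40.0)
  sr <- build_structured_report(r, c(DCM_UID$segmentation_storage, "1.2.840.99.42.1"),
                                source_study_uid = "1.2.840.99.42",
                                source_series_uid = "1.2.840.99.42.2")
  expect_identical(ds_get(sr, "StudyInstanceUID"), "1.2.840.99.42")
  m <- sr_measurements(sr)
  expect_identical(m$volume_ml, 40.0)
  expect_identical(m$summary, "Spleen volume: 40.0 mL")
  expect_identical(attr(m, "seg_sop_instance_uid"), "1.2.840.99.42.1")
  expect_identical(attr(m, "study_uid"), "1.2.840.99.42")
  # units are coded UCUM millilitres
  num <- ds_get(ds_get(sr, "ContentSequence")[[1]], "ContentSequence")[[2]]
  units <- ds_get(ds_get(num, "MeasuredValueSequence")[[1]], "MeasurementUnitsCodeSequence")[[1]]
  expect_identical(ds_get(units, "CodeValue"), "ml")
  expect_identical(ds_get(units, "CodingSchemeDesignator"), "UCUM")
})

test_that("SR measurement groups are ordered by ascending label id", {
  labels <- array(0L, dim = c(8, 8, 4))
  labels[1:2, 1:2, 1] <- 1L; labels[5:6, 5:6, 2] <- 2L
  lv <- label_volume(labels, unit_geom(c(8L, 8L, 4L)))
  r <- compute_volumes(lv, list(segment_descriptor(2L, "beta"), segment_descriptor(1L, "alpha")))
  sr <- build_structured_report(r, c(DCM_UID$segmentation_storage, "1.2.3.1"),
                                "1.2.3", "1.2.3.2")
  m <- sr_measurements(sr)
  expect_identical(m$segment_label, c("alpha", "beta"))
})

test_that("SR construction validates its inputs", {
  labels <- array(0L, dim = c(4, 4, 2)); labels[1, 1, 1] <- 1L
  r <- compute_volumes(label_volume(labels, unit_geom(c(4L, 4L, 2L))),
                       list(segment_descriptor(1L, "x")))
  expect_error(build_structured_report(r[0, ], c("1.2", "1.3"), "1.2", "1.3"),
               class = "ctqv_validation_error")
  expect_error(build_structured_report(r, c("1.2"), "1.2", "1.3"),
               class = "ctqv_validation_error")
})
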