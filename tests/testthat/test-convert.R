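test_that("sort_series orders by slice-normal projection with stated tie-breaks", {
  set.seed(51)
  zs <- seq(0, 30, by = 3)
  recs <- lapply(seq_along(zs), function(i) {
    tiny_ct_record("1.2.840.99.30", paste0("1.2.840.99.30.", i),
                   z = zs[i], instance_number = i)
  })
  shuffled <- recs[sample(seq_along(recs))]
  sorted <- sort_series(shuffled)
  got_z <- vapply(sorted, function(r) r$image_position_patient[3], 0)
  # oracle for pure-axial orientation: plain sort by z
  expect_identical(got_z, sort(zs))

  expect_identical(sort_series(recs[1]), recs[1])

  # identical positions: instance_number then SOP UID break the tie
  a <- tiny_ct_record("1.2.840.99.31", "1.2.840.99.31.9", z = 0, instance_number = 2L)
  b <- tiny_ct_record("1.2.840.99.31", "1.2.840.99.31.5", z = 0, instance_number = 1L)
  sorted <- sort_series(list(a, b))
  expect_identical(vapply(sorted, function(r) r$instance_number, 1L), c(1L, 2L))
})

test_that("sort_series rejects mixed orientations and missing positions", {
  a <- tiny_ct_record("1.2.840.99.32", "1.2.840.99.32.1")
  b <- tiny_ct_record("1.2.840.99.32", "1.2.840.99.32.2",
                      iop = c(0, 1, 0, 1, 0, 0))
  expect_error(sort_series(list(a, b)), class = "ctqv_geometry_error")
  ds <- tiny_ct_dataset("1.2.840.99.32", "1.2.840.99.32.3")
  ds <- ds_del(ds, "ImagePositionPatient")
  expect_error(sort_series(list(a, dicom_instance_record(ds))),
               class = "ctqv_geometry_error")
})

test_that("the rescale transform maps stored values to HU", {
  mk <- function(stored, slope, intercept) {
    ds <- tiny_ct_dataset("1.2.840.99.33", "1.2.840.99.33.1", stored_value = stored)
    ds <- ds_set(ds, "RescaleSlope", slope)
    ds <- ds_set(ds, "RescaleIntercept", intercept)
    build_volume(list(dicom_instance_record(ds)))$voxels[1, 1, 1]
  }
  expect_identical(mk(1024L, 1, -1024), 0)
  expect_identical(mk(100L, 2, -10), 190)
})

test_that("HU mapping is affine and monotone in stored values for positive slope", {
  stored <- c(0L, 7L, 512L, 1024L, 4095L)
  hu <- vapply(stored, function(s) {
    ds <- tiny_ct_dataset("1.2.840.99.34", "1.2.840.99.34.1", stored_value = s)
    build_volume(list(dicom_instance_record(ds)))$voxels[1, 1, 1]
  }, 0)
  expect_identical(hu, as.numeric(stored) - 1024)
  expect_true(all(diff(hu) > 0))
})

test_that("non-uniform inter-slice spacing is a named geometry error; uniform passes", {
  mk_series <- function(zs) {
    lapply(seq_along(zs), function(i) {
      tiny_ct_record("1.2.840.99.35", paste0("1.2.840.99.35.", i),
                     z = zs[i], instance_number = i)
    })
  }
  # gap 6 vs median 3: brute-force increments are (3, 3, 6)
  err <- tryCatch(build_volume(mk_series(c(0, 3, 6, 12))),
                  ctqv_geometry_error = function(e) e)
  expect_s3_class(err, "ctqv_geometry_error")
  expect_match(conditionMessage(err), "6")
  vol <- build_volume(mk_series(c(0, 3, 6, 9)))
  expect_equal(vol$geometry$spacing[3], 3)
  # single slice: falls back to SliceThickness
  vol1 <- build_volume(mk_series(0))
  expect_equal(vol1$geometry$spacing[3], 3)
})

test_that("the NIfTI affine encodes the LPS->RAS sign convention and spacing", {
  geom <- volume_geometry(origin = c(0, 0, 0), row_direction = c(1, 0, 0),
                          column_direction = c(0, 1, 0),
                          spacing = c(0.8, 0.8, 3.0), shape = c(4L, 4L, 2L))
  aff <- nifti_affine(geom)
  expect_equal(apply(aff[1:3, 1:3], 2, function(v) sqrt(sum(v^2))), c(0.8, 0.8, 3.0))
  # diag(-spacing, -spacing, spacing) up to column ordering (row index varies
  # along the anatomical y axis for an axial identity orientation)
  expect_equal(aff[1:3, c(2, 1, 3)], diag(c(-0.8, -0.8, 3.0)))
  geom1 <- volume_geometry(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 1), c(2L, 2L, 2L))
  expect_equal(nifti_affine(geom1)[, c(2, 1, 3, 4)], diag(c(-1, -1, 1, 1)))
})

test_that("NIfTI write/read round-trips voxels bit-exactly and geometry within 1e-4 mm", {
  set.seed(52)
  spec <- small_lesion_spec(shape = c(20L, 24L, 6L), spacing = c(0.8, 0.9))
  g <- generate_series(spec, tempfile())
  vol <- build_volume(sort_series(g$records))
  f <- tempfile(fileext = ".nii.gz")
  write_nifti(vol, f)
  back <- read_nifti_volume(f)
  expect_identical(back$voxels, vol$voxels)
  expect_true(geom_equal(back$geometry, vol$geometry, tol = 1e-6))
})

test_that("read_nifti_labels validates co-registration and label values distinctly", {
  set.seed(53)
  geom <- volume_geometry(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 3), c(8L, 8L, 4L))
  labels <- array(0L, dim = c(8, 8, 4)); labels[3:5, 3:5, 2] <- 1L
  lv <- label_volume(labels, geom)
  f <- tempfile(fileext = ".nii.gz")
  write_nifti_labels(lv, f)
  back <- read_nifti_labels(f, geom)
  expect_identical(back$labels, lv$labels)
  expect_identical(back$label_ids_present, 1L)

  # transposed shape
  bad_geom <- volume_geometry(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 3), c(8L, 4L, 8L))
  expect_error(read_nifti_labels(f, bad_geom), class = "ctqv_shape_mismatch")
  # shifted affine
  shifted <- volume_geometry(c(5, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 3), c(8L, 8L, 4L))
  expect_error(read_nifti_labels(f, shifted), class = "ctqv_affine_mismatch")

  # near-integer values accepted and rounded; truly fractional rejected
  img <- RNifti::readNifti(f)
  arr <- array(as.numeric(img), dim = dim(img))
  arr[3, 3, 2] <- 1.0000001
  v <- image_volume(arr, geom)
  f2 <- tempfile(fileext = ".nii.gz")
  write_nifti(v, f2)
  expect_identical(read_nifti_labels(f2, geom)$labels, lv$labels)
  arr[3, 3, 2] <- 0.5
  f3 <- tempfile(fileext = ".nii.gz")
  write_nifti(image_volume(arr, geom), f3)
  expect_error(read_nifti_labels(f3, geom), class = "ctqv_label_value_error")
  arr[3, 3, 2] <- -1
  f4 <- tempfile(fileext = ".nii.gz")
  write_nifti(image_volume(arr, geom), f4)
  expect_error(read_nifti_labels(f4, geom), class = "ctqv_label_value_error")
})

test_that("randomized oblique geometries survive DICOM -> volume -> NIfTI -> read-back", {
  set.seed(54)
  for (i in 1:20) {
    o <- random_orientation()
    geom <- volume_geometry(origin = runif(3, -100, 100),
                            row_direction = o$row, column_direction = o$col,
                            spacing = runif(3, 0.4, 5), shape = c(6L, 5L, 4L))
    src <- source_series_for_geometry(geom)
    vol <- build_volume(sort_series(src))
    expect_true(geom_equal(vol$geometry, geom, tol = 1e-4))
    f <- tempfile(fileext = ".nii.gz")
    write_nifti(vol, f)
    back <- read_nifti_volume(f)
    expect_true(geom_equal(back$geometry, geom, tol = 1e-4))
    unlink(f)
  }
})
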