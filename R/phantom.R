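# Synthetic CT phantom generator: axial DICOM series with analytically known
# lesion volumes and a voxelized ground-truth mask. This is the test
# substrate standing in for clinical studies: it emulates the series shape
# of portal-venous abdominopelvic CT (hundreds of 512x512 axial slices at
# 3 mm spacing) with contiguous hyperdense lesions, not realistic anatomy.

#' Specify a synthetic CT phantom
#'
#' @param shape Integer 3-vector (rows, cols, slices).
#' @param pixel_spacing Numeric 2-vector (between-rows, between-columns), mm.
#' @param slice_spacing Slice thickness and inter-slice spacing, mm
#'   (contiguous acquisition: the two are equal).
#' @param background_hu Background attenuation, HU.
#' @param lesions List of lesions; each a list with `kind` ("ellipsoid" or
#'   "cuboid"), `center` (LPS mm), `semi_axes` (ellipsoid) or `half_extents`
#'   (cuboid) in mm along (x, y, z), `hu`, and `label_id` (unique, > 0).
#'   Later lesions overwrite earlier ones where they overlap.
#' @param origin LPS position of the center of voxel (0,0,0), mm.
#' @param series_description Series description written into every slice.
#' @param patient_name,patient_id Synthetic identity, used by
#'   de-identification tests.
#' @param noise_sd Gaussian noise SD in HU added to the image (never to the
#'   truth mask); 0 disables noise.
#' @param seed RNG seed for noise and UID generation.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 20L),
                         pixel_spacing = c(1, 1),
                         slice_spacing = 3,
                         background_hu = 20,
                         lesions = list(),
                         origin = c(0, 0, 0),
                         series_description = "ABD PV PORTAL 3MM",
                         patient_name = "DOE^JANE",
                         patient_id = "PHANTOM-001",
                         noise_sd = 0,
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0L),
            length(pixel_spacing) == 2L, all(pixel_spacing > 0),
            slice_spacing > 0, noise_sd >= 0)
  ids <- vapply(lesions, function(l) as.integer(l$label_id), 1L)
  if (anyDuplicated(ids)) stop("lesion label_ids must be unique", call. = FALSE)
  spec <- structure(list(shape = shape,
                         pixel_spacing = as.numeric(pixel_spacing),
                         slice_spacing = as.numeric(slice_spacing),
                         background_hu = background_hu,
                         lesions = lesions,
                         origin = as.numeric(origin),
                         series_description = series_description,
                         patient_name = patient_name,
                         patient_id = patient_id,
                         noise_sd = noise_sd,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  .check_lesion_bounds(spec)
  spec
}

.phantom_geometry <- function(spec) {
  volume_geometry(origin = spec$origin,
                  row_direction = c(1, 0, 0),
                  column_direction = c(0, 1, 0),
                  spacing = c(spec$pixel_spacing, spec$slice_spacing),
                  shape = spec$shape)
}

.lesion_extents <- function(lesion) {
  if (identical(lesion$kind, "ellipsoid")) as.numeric(lesion$semi_axes)
  else as.numeric(lesion$half_extents)
}

.check_lesion_bounds <- function(spec) {
  geom <- .phantom_geometry(spec)
  # volume bounds: voxel centers span origin .. origin + (shape-1)*step,
  # extended by half a voxel on each side (axial identity orientation:
  # x <- columns, y <- rows, z <- slices)
  step <- c(spec$pixel_spacing[2], spec$pixel_spacing[1], spec$slice_spacing)
  extent_vox <- c(spec$shape[2], spec$shape[1], spec$shape[3])
  lo <- geom$origin - step / 2
  hi <- geom$origin + (extent_vox - 1) * step + step / 2
  for (lesion in spec$lesions) {
    ctr <- as.numeric(lesion$center); ext <- .lesion_extents(lesion)
    if (any(ctr - ext < lo) || any(ctr + ext > hi)) {
      stop(sprintf("lesion label_id %d extends outside the volume bounds",
                   as.integer(lesion$label_id)), call. = FALSE)
    }
  }
  invisible(spec)
}

#' Analytic lesion volumes of a phantom in mL
#'
#' Ellipsoid: 4/3 pi a b c; cuboid: 8 hx hy hz (mm^3), converted to mL.
#'
#' @param spec A [phantom_spec()].
#' @return Named numeric vector, names = label ids, values in mL.
#' @export
phantom_analytic_volumes_ml <- function(spec) {
  if (!length(spec$lesions)) return(stats::setNames(numeric(0), character(0)))
  vols <- vapply(spec$lesions, function(l) {
    e <- .lesion_extents(l)
    mm3 <- if (identical(l$kind, "ellipsoid")) 4 / 3 * pi * prod(e) else 8 * prod(e)
    mm3 / 1000
  }, 0)
  stats::setNames(vols, vapply(spec$lesions, function(l) as.character(l$label_id), ""))
}

# membership arrays by exhaustive voxel-center inclusion; separable terms
# keep this vectorized (axis-aligned shapes only)
.lesion_mask <- function(spec, lesion) {
  geom <- .phantom_geometry(spec)
  nr <- spec$shape[1]; nc <- spec$shape[2]; ns <- spec$shape[3]
  xs <- geom$origin[1] + (seq_len(nc) - 1) * spec$pixel_spacing[2]
  ys <- geom$origin[2] + (seq_len(nr) - 1) * spec$pixel_spacing[1]
  zs <- geom$origin[3] + (seq_len(ns) - 1) * spec$slice_spacing
  ctr <- as.numeric(lesion$center); ext <- .lesion_extents(lesion)
  mask <- array(FALSE, dim = spec$shape)
  if (identical(lesion$kind, "ellipsoid")) {
    tx <- ((xs - ctr[1]) / ext[1])^2
    ty <- ((ys - ctr[2]) / ext[2])^2
    plane <- outer(ty, tx, "+")                       # rows x cols
    tz <- ((zs - ctr[3]) / ext[3])^2
    for (k in seq_len(ns)) mask[, , k] <- plane + tz[k] <= 1
  } else {
    inx <- abs(xs - ctr[1]) <= ext[1]
    iny <- abs(ys - ctr[2]) <= ext[2]
    plane <- outer(iny, inx, "&")
    inz <- abs(zs - ctr[3]) <= ext[3]
    for (k in seq_len(ns)) mask[, , k] <- plane & inz[k]
  }
  mask
}

#' Voxelized ground-truth label volume of a phantom
#'
#' Voxel membership is by center inclusion (no anti-aliasing), the same rule
#' the generator uses for image intensities, so the truth mask and a
#' threshold segmentation of a noise-free phantom agree voxel for voxel.
#'
#' @param spec A [phantom_spec()].
#' @return A [label_volume()].
#' @export
phantom_truth <- function(spec) {
  labels <- array(0L, dim = spec$shape)
  for (lesion in spec$lesions) {
    m <- .lesion_mask(spec, lesion)
    labels[m] <- as.integer(lesion$label_id)
  }
  label_volume(labels, .phantom_geometry(spec))
}

#' Generate a phantom CT series as DICOM Part-10 files
#'
#' Writes one CT file per slice (16-bit stored pixels, rescale slope 1,
#' intercept -1024) with a consistent fresh UID tree and constant slice
#' position increments, plus the ground-truth mask as NIfTI
#' (`truth_mask.nii.gz`) for cross-checks.
#'
#' @param spec A [phantom_spec()].
#' @param out_dir Output directory (created if missing); one `.dcm` per slice.
#' @return A list: `records` (list of [dicom_instance_record()] in instance
#'   order), `truth` ([label_volume()]), `analytic_volumes_ml` (named
#'   vector), `paths` (slice files), `series_instance_uid`, `geometry`.
#' @export
generate_series <- function(spec, out_dir = tempfile("phantom")) {
  stopifnot(inherits(spec, "phantom_spec"))
  .check_lesion_bounds(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  geom <- .phantom_geometry(spec)
  truth <- phantom_truth(spec)

  hu <- array(spec$background_hu, dim = spec$shape)
  for (lesion in spec$lesions) hu[.lesion_mask(spec, lesion)] <- lesion$hu

  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
  set.seed(spec$seed)
  if (spec$noise_sd > 0) {
    hu <- hu + stats::rnorm(length(hu), sd = spec$noise_sd)
  }
  stored <- pmin(pmax(round(hu) + 1024L, 0L), 32767L)
  storage.mode(stored) <- "integer"

  study_uid <- new_uid(); series_uid <- new_uid(); for_uid <- new_uid()
  ns <- spec$shape[3]
  sop_uids <- replicate(ns, new_uid())
  paths <- file.path(out_dir, sprintf("slice_%04d.dcm", seq_len(ns)))
  records <- vector("list", ns)

  for (k in seq_len(ns)) {
    ipp <- geom$origin + (k - 1) * spec$slice_spacing * geom$slice_direction
    ds <- ds_new()
    ds <- ds_set(ds, "SpecificCharacterSet", "ISO_IR 100")
    ds <- ds_set(ds, "ImageType", c("DERIVED", "SECONDARY", "AXIAL"))
    ds <- ds_set(ds, "SOPClassUID", DCM_UID$ct_image_storage)
    ds <- ds_set(ds, "SOPInstanceUID", sop_uids[k])
    ds <- ds_set(ds, "StudyDate", "20210517")
    ds <- ds_set(ds, "StudyTime", "120000")
    ds <- ds_set(ds, "AccessionNumber", "ACC-PHANTOM-1")
    ds <- ds_set(ds, "Modality", "CT")
    ds <- ds_set(ds, "Manufacturer", "ctqv phantom")
    ds <- ds_set(ds, "InstitutionName", "Synthetic General Hospital")
    ds <- ds_set(ds, "ReferringPhysicianName", "REF^PHYSICIAN")
    ds <- ds_set(ds, "SeriesDescription", spec$series_description)
    ds <- ds_set(ds, "OperatorsName", "TECH^ONE")
    ds <- ds_set(ds, "PatientName", spec$patient_name)
    ds <- ds_set(ds, "PatientID", spec$patient_id)
    ds <- ds_set(ds, "PatientBirthDate", "19800229")
    ds <- ds_set(ds, "PatientSex", "O")
    ds <- ds_set(ds, "SliceThickness", spec$slice_spacing)
    ds <- ds_set(ds, "StudyInstanceUID", study_uid)
    ds <- ds_set(ds, "SeriesInstanceUID", series_uid)
    ds <- ds_set(ds, "StudyID", "1")
    ds <- ds_set(ds, "SeriesNumber", 2L)
    ds <- ds_set(ds, "InstanceNumber", k)
    ds <- ds_set(ds, "ImagePositionPatient", ipp)
    ds <- ds_set(ds, "ImageOrientationPatient", c(geom$row_direction, geom$column_direction))
    ds <- ds_set(ds, "FrameOfReferenceUID", for_uid)
    ds <- ds_set(ds, "SamplesPerPixel", 1L)
    ds <- ds_set(ds, "PhotometricInterpretation", "MONOCHROME2")
    ds <- ds_set(ds, "Rows", spec$shape[1])
    ds <- ds_set(ds, "Columns", spec$shape[2])
    ds <- ds_set(ds, "PixelSpacing", spec$pixel_spacing)
    ds <- ds_set(ds, "BitsAllocated", 16L)
    ds <- ds_set(ds, "BitsStored", 16L)
    ds <- ds_set(ds, "HighBit", 15L)
    ds <- ds_set(ds, "PixelRepresentation", 0L)
    ds <- ds_set(ds, "RescaleIntercept", -1024)
    ds <- ds_set(ds, "RescaleSlope", 1)
    # DICOM pixel order is row-major (column index fastest)
    pix <- writeBin(as.vector(t(stored[, , k])), raw(), size = 2, endian = "little")
    ds <- ds_set(ds, "PixelData", pix)
    dcm_write(ds, paths[k])
    records[[k]] <- dicom_instance_record(ds)
  }

  truth_path <- file.path(out_dir, "truth_mask.nii.gz")
  write_nifti_labels(truth, truth_path)

  list(records = records,
       truth = truth,
       analytic_volumes_ml = phantom_analytic_volumes_ml(spec),
       paths = paths,
       truth_path = truth_path,
       series_instance_uid = series_uid,
       geometry = geom)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(seed) {
  if (is.null(seed)) return(invisible())
  assign(".Random.seed", seed, envir = globalenv())
}

#' Randomized phantom at the study's series scale
#'
#' Draws a phantom whose series shape matches the portal-venous CT studies
#' the pipeline targets: 512 x 512 axial grids of 91-203 slices at 3 mm
#' section thickness, with one or two hyperdense ellipsoid lesions whose
#' analytic volumes fall in 28.0-924.7 mL. Deterministic under `seed`.
#'
#' @param seed Integer seed.
#' @param grid Grid side length (default 512; reduce for quick runs while
#'   keeping the slice-count and volume distributions).
#' @return A [phantom_spec()].
#' @export
study_scale_spec <- function(seed, grid = 512L) {
  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
  set.seed(seed)
  n_slices <- sample(91:203, 1L)
  pixel_mm <- 400 / grid                    # ~40 cm abdominal field of view
  n_lesions <- sample(1:2, 1L)
  z_extent <- (n_slices - 1) * 3
  x_mid <- (grid - 1) * pixel_mm / 2
  lesions <- list()
  boxes <- list()
  for (i in seq_len(n_lesions)) {
    repeat {
      v_ml <- stats::runif(1, 28, 924.7)
      r1 <- stats::runif(1, 0.7, 1.3); r2 <- stats::runif(1, 0.7, 1.3)
      b <- (v_ml * 1000 * 3 / (4 * pi) / (r1 * r2))^(1 / 3)
      a <- r1 * b; cc <- r2 * b
      ctr <- c(x_mid + stats::runif(1, -20, 20),
               x_mid + stats::runif(1, -20, 20),
               stats::runif(1, cc + 3, z_extent - cc - 3))
      if (ctr[3] - cc < 1.5 || ctr[3] + cc > z_extent - 1.5) next
      box <- c(ctr[3] - cc, ctr[3] + cc)
      clash <- any(vapply(boxes, function(bx) box[1] <= bx[2] && bx[1] <= box[2], TRUE))
      if (!clash) break
    }
    boxes[[i]] <- box
    lesions[[i]] <- list(kind = "ellipsoid", center = ctr,
                         semi_axes = c(a, b, cc), hu = 60,
                         label_id = i)
  }
  phantom_spec(shape = c(grid, grid, n_slices),
               pixel_spacing = c(pixel_mm, pixel_mm),
               slice_spacing = 3,
               background_hu = 20,
               lesions = lesions,
               series_description = "ABD PV PORTAL 3MM",
               noise_sd = 0,
               seed = seed)
}
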