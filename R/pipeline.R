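# Pipeline orchestration: a fully local one-command run over a directory of
# DICOM series, and an in-process loopback deployment wiring the router, the
# processing host and a stub archive with a simulated monotonic clock.

.log_record <- function(log_env, series, stage, t0, t1, note = "") {
  log_env$rows[[length(log_env$rows) + 1L]] <-
    tibble::tibble(series_instance_uid = series, stage = stage,
                   t_start = t0, t_end = t1, note = note)
  invisible(NULL)
}

# The processing host's work for one completed, sorted series:
# convert -> NIfTI -> segment -> validate mask -> encode SEG.
.process_series <- function(sorted_records, backend, descriptors, artifacts_dir = NULL) {
  volume <- build_volume(sorted_records)
  nifti_path <- if (!is.null(artifacts_dir)) file.path(artifacts_dir, "image.nii.gz")
                else tempfile(fileext = ".nii.gz")
  write_nifti(volume, nifti_path)
  labels <- segment_volume(volume, backend)
  mask_path <- if (!is.null(artifacts_dir)) file.path(artifacts_dir, "mask.nii.gz")
               else tempfile(fileext = ".nii.gz")
  write_nifti_labels(labels, mask_path)
  labels <- read_nifti_labels(mask_path, volume$geometry)
  if (!length(labels$label_ids_present)) {
    return(list(seg = structure(list(source_series_uid = sorted_records[[1]]$series_instance_uid),
                                class = "empty_segmentation"),
                volume = volume, labels = labels,
                nifti_path = nifti_path, mask_path = mask_path))
  }
  present <- labels$label_ids_present
  ids <- vapply(descriptors, function(d) d$label_id, 1L)
  seg <- encode_seg(labels, descriptors[ids %in% present], sorted_records)
  list(seg = seg, volume = volume, labels = labels,
       nifti_path = nifti_path, mask_path = mask_path)
}

#' Run the full pipeline locally on a directory of DICOM files
#'
#' One command, no network: filter, anonymize, sort, convert to NIfTI,
#' segment, validate the mask, encode the SEG, compute volumetry from the
#' SEG pixel data, and write the SR — per series, with one series' failure
#' not aborting the others. All artifacts land under `out_dir`, and a JSON
#' run summary is written alongside them.
#'
#' @param config A [load_config()] result, or a `pipeline_config`.
#' @param input_dir Directory holding at least one DICOM series (searched
#'   recursively for `.dcm` files).
#' @param out_dir Output directory.
#' @return A `run_summary` list: `series` (tibble: one row per series with
#'   status and artifact paths), `volumes` (tibble of all volumetry rows),
#'   `log` (stage log tibble), `summary_path`.
#' @export
run_local <- function(config, input_dir, out_dir = tempfile("ctqv_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  files <- list.files(input_dir, pattern = "\\.dcm$", recursive = TRUE, full.names = TRUE)
  if (!length(files)) {
    stop(errorCondition(paste0("no DICOM files found under ", input_dir),
                        class = c("ctqv_validation_error", "ctqv_error")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  descriptors <- read_segment_attributes(config$segment_attributes_path)
  profile <- config$anonymization
  map <- uid_map()
  log_env <- new.env(); log_env$rows <- list()

  records <- lapply(files, function(f) {
    tryCatch(read_instance(f), error = function(e) NULL)
  })
  records <- records[!vapply(records, is.null, TRUE)]
  if (!length(records)) {
    stop(errorCondition("no readable DICOM instances in input_dir",
                        class = c("ctqv_validation_error", "ctqv_error")))
  }
  by_series <- split(records, vapply(records, function(r) r$series_instance_uid, ""))

  series_rows <- list()
  all_volumes <- list()
  for (series_uid in names(by_series)) {
    recs <- by_series[[series_uid]]
    if (!match_series(recs[[1]], config$series_filter)) {
      series_rows[[series_uid]] <- tibble::tibble(
        series_instance_uid = series_uid, n_instances = length(recs),
        status = "filtered", anonymized_series_uid = NA_character_,
        seg_path = NA_character_, sr_path = NA_character_,
        nifti_path = NA_character_, error = NA_character_)
      next
    }
    row <- tryCatch({
      t0 <- proc.time()[["elapsed"]]
      anon <- lapply(recs, anonymize_instance, profile = profile, map = map)
      sorted <- sort_series(anon)
      anon_uid <- sorted[[1]]$series_instance_uid
      .log_record(log_env, anon_uid, "anonymize", t0, proc.time()[["elapsed"]])
      series_dir <- file.path(out_dir, anon_uid)
      dir.create(series_dir, showWarnings = FALSE)

      t0 <- proc.time()[["elapsed"]]
      result <- .process_series(sorted, config$backend, descriptors, series_dir)
      .log_record(log_env, anon_uid, "convert+segment+encode", t0, proc.time()[["elapsed"]])

      if (inherits(result$seg, "empty_segmentation")) {
        tibble::tibble(series_instance_uid = series_uid, n_instances = length(recs),
                       status = "empty_segmentation", anonymized_series_uid = anon_uid,
                       seg_path = NA_character_, sr_path = NA_character_,
                       nifti_path = result$nifti_path, error = NA_character_)
      } else {
        t0 <- proc.time()[["elapsed"]]
        decoded <- decode_seg(result$seg)
        volumes <- compute_volumes(decoded$labels, decoded$descriptors)
        sr <- build_structured_report(
          volumes,
          seg_reference = c(ds_get(result$seg, "SOPClassUID"), ds_get(result$seg, "SOPInstanceUID")),
          source_study_uid = ds_get(result$seg, "StudyInstanceUID"),
          source_series_uid = anon_uid)
        seg_path <- file.path(series_dir, "seg.dcm")
        sr_path <- file.path(series_dir, "sr.dcm")
        dcm_write(result$seg, seg_path)
        dcm_write(sr, sr_path)
        .log_record(log_env, anon_uid, "volumetry+sr", t0, proc.time()[["elapsed"]])
        volumes$series_instance_uid <- anon_uid
        all_volumes[[anon_uid]] <- volumes
        tibble::tibble(series_instance_uid = series_uid, n_instances = length(recs),
                       status = "processed", anonymized_series_uid = anon_uid,
                       seg_path = seg_path, sr_path = sr_path,
                       nifti_path = result$nifti_path, error = NA_character_)
      }
    }, ctqv_error = function(e) {
      tibble::tibble(series_instance_uid = series_uid, n_instances = length(recs),
                     status = "error", anonymized_series_uid = NA_character_,
                     seg_path = NA_character_, sr_path = NA_character_,
                     nifti_path = NA_character_,
                     error = paste0(class(e)[1], ": ", conditionMessage(e)))
    })
    series_rows[[series_uid]] <- row
  }

  series_tbl <- do.call(rbind, unname(series_rows))
  volumes_tbl <- if (length(all_volumes)) do.call(rbind, unname(all_volumes)) else NULL
  log_tbl <- if (length(log_env$rows)) do.call(rbind, log_env$rows) else NULL
  summary <- list(series = series_tbl, volumes = volumes_tbl, log = log_tbl)
  summary_path <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(list(series = series_tbl, volumes = volumes_tbl),
                       summary_path, auto_unbox = TRUE, digits = NA, na = "null")
  summary$summary_path <- summary_path
  class(summary) <- "run_summary"
  summary
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("<run_summary: %d series (%s)>\n", nrow(x$series),
              paste(sprintf("%d %s", table(x$series$status),
                            names(table(x$series$status))), collapse = ", ")))
  if (!is.null(x$volumes)) {
    for (i in seq_len(nrow(x$volumes))) {
      cat(sprintf("  %s: %.1f mL\n", x$volumes$segment_label[i], x$volumes$volume_ml[i]))
    }
  }
  invisible(x)
}

#' Run the networked deployment in-process on a simulated clock
#'
#' Wires the three nodes of a shadow deployment — the router, the
#' processing host, and the archive — as in-process peers and drives them
#' from an event trace of instance arrivals on a simulated monotonic clock.
#' Instances are C-STORE'd to the router at their arrival times; a periodic
#' tick sweeps series whose quiet period has reached the configured
#' timeout; completed series are dispatched to archive and processor; the
#' processor converts, segments and returns a SEG; the router derives the
#' SR and forwards SEG + SR to the archive.
#'
#' @param config A `pipeline_config`.
#' @param arrivals Data frame with columns `time` (seconds, simulated) and
#'   `path` (Part-10 file), one row per C-STORE.
#' @param tick Sweep period of the completion timer, simulated seconds.
#' @param stop_time Stop the clock early (simulates shutdown; series still
#'   accumulating stay parked in the spool for a later
#'   [resume_from_spool()]).
#' @param archive_dir,processor_dir,spool_dir Storage locations (defaults
#'   under `tempdir()`).
#' @return A `loopback_result`: `archive` peer, `router`, `reports`,
#'   `volumes`, `spool_dir`, `clock`.
#' @export
serve_loopback <- function(config, arrivals, tick = 1,
                           stop_time = Inf,
                           archive_dir = tempfile("archive_"),
                           processor_dir = tempfile("processor_"),
                           spool_dir = config$spool_dir %||% tempfile("spool_")) {
  stopifnot(inherits(config, "pipeline_config"))
  arrivals <- arrivals[order(arrivals$time), , drop = FALSE]
  descriptors <- read_segment_attributes(config$segment_attributes_path)
  archive <- dir_peer(config$archive$ae_title, archive_dir)
  processor <- dir_peer(config$processor$ae_title, processor_dir)
  dir.create(spool_dir, recursive = TRUE, showWarnings = FALSE)
  router <- dicom_router(config$series_filter, config$anonymization,
                         timeout_seconds = config$timeout_seconds,
                         retry_delay = 0)
  volumes <- list()
  next_arrival <- 1L
  clock <- 0
  n <- nrow(arrivals)

  ingest_one <- function(i, now) {
    status <- router_ingest(router, arrivals$path[i], now)
    if (identical(status, DIMSE_SUCCESS)) {
      # park the (anonymized) instance in the spool for crash recovery
      for (uid in names(router$buffers)) {
        buf <- router$buffers[[uid]]
        if (identical(buf$state, "accumulating")) {
          sdir <- file.path(spool_dir, uid)
          if (!dir.exists(sdir)) dir.create(sdir)
          existing <- basename(list.files(sdir))
          for (sop in setdiff(names(buf$instances), sub("\\.dcm$", "", existing))) {
            dcm_write(buf$instances[[sop]]$dataset, file.path(sdir, paste0(sop, ".dcm")))
          }
        }
      }
    }
    status
  }

  repeat {
    # deliver arrivals due at or before the current clock
    while (next_arrival <= n && arrivals$time[next_arrival] <= clock) {
      ingest_one(next_arrival, arrivals$time[next_arrival])
      next_arrival <- next_arrival + 1L
    }
    ready <- router_sweep_completions(router, clock)
    for (buf in ready) {
      router_dispatch(router, buf, archive, processor, now = clock)
      # processing host reacts to the completed transfer: one series at a
      # time (serialized), then returns the SEG to the router
      sorted <- sort_series(unname(router$buffers[[buf$series_instance_uid]]$instances))
      result <- .process_series(sorted, config$backend, descriptors)
      unlink(file.path(spool_dir, buf$series_instance_uid), recursive = TRUE)
      if (!inherits(result$seg, "empty_segmentation")) {
        processor$store(result$seg)
        handled <- router_handle_returned_seg(router, result$seg, archive)
        if (!is.null(handled$volumes)) {
          v <- handled$volumes
          v$series_instance_uid <- buf$series_instance_uid
          volumes[[length(volumes) + 1L]] <- v
        }
      }
    }
    done <- next_arrival > n &&
      !any(vapply(router$buffers, function(b) !identical(b$state, "dispatched"), TRUE))
    if (done || clock >= stop_time) break
    clock <- clock + tick
  }

  structure(list(archive = archive, processor = processor, router = router,
                 reports = router_reports(router),
                 volumes = if (length(volumes)) do.call(rbind, volumes) else NULL,
                 spool_dir = spool_dir, clock = clock),
            class = "loopback_result")
}

#' Resume a loopback deployment from its spool directory
#'
#' Re-ingests every series parked under `spool_dir` (anonymized Part-10
#' files written before a shutdown) into a fresh loopback run, completing
#' their processing.
#'
#' @param config A `pipeline_config`.
#' @param spool_dir Spool directory of an interrupted [serve_loopback()].
#' @param tick Sweep period, simulated seconds.
#' @return A `loopback_result`.
#' @export
resume_from_spool <- function(config, spool_dir, tick = 1) {
  files <- list.files(spool_dir, pattern = "\\.dcm$", recursive = TRUE, full.names = TRUE)
  if (!length(files)) {
    stop(errorCondition("spool directory holds no parked instances",
                        class = c("ctqv_validation_error", "ctqv_error")))
  }
  arrivals <- data.frame(time = 0, path = files, stringsAsFactors = FALSE)
  serve_loopback(config, arrivals, tick = tick, spool_dir = tempfile("spool_"))
}
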