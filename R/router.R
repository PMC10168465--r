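# The store-and-forward router: accepts C-STORE'd CT instances, filters
# config-specified series, anonymizes, detects series completion by receive
# timeout, forwards to an archive peer and a processing peer, and later
# receives the SEG back, derives the SR, and forwards both onward.
#
# Transport note: peers implement function-call C-STORE semantics (see
# [dir_peer()]); the DIMSE wire protocol itself is outside this package and
# tests use in-process stub peers, mirroring a shadow deployment where the
# archive is an external system.

DIMSE_SUCCESS <- 0x0000
DIMSE_CANNOT_UNDERSTAND <- 0xC000

#' Network address of a DICOM application entity
#' @param ae_title AE title (non-empty, <= 16 chars, no surrounding spaces).
#' @param host Hostname or IP.
#' @param port Integer 1-65535.
#' @return A `node_address`.
#' @export
node_address <- function(ae_title, host = "127.0.0.1", port = 104L) {
  if (!is.character(ae_title) || !nzchar(ae_title) || nchar(ae_title) > 16L ||
      grepl("^\\s|\\s$", ae_title)) {
    stop("ae_title must be 1-16 characters with no leading/trailing spaces", call. = FALSE)
  }
  port <- as.integer(port)
  if (is.na(port) || port < 1L || port > 65535L) stop("port must be in 1..65535", call. = FALSE)
  structure(list(ae_title = ae_title, host = host, port = port), class = "node_address")
}

#' Series filter
#'
#' @param patterns Non-empty character vector of patterns.
#' @param mode `"substring"`, `"regex"` or `"exact"`.
#' @param match_field Which attribute to match: `"series_description"`,
#'   `"series_number"` or `"modality"`.
#' @param case_sensitive Default `FALSE`.
#' @return A `series_filter`.
#' @export
series_filter <- function(patterns, mode = c("substring", "regex", "exact"),
                          match_field = c("series_description", "series_number", "modality"),
                          case_sensitive = FALSE) {
  mode <- match.arg(mode); match_field <- match.arg(match_field)
  patterns <- as.character(patterns)
  if (!length(patterns) || any(!nzchar(patterns))) {
    stop("patterns must be a non-empty character vector", call. = FALSE)
  }
  if (mode == "regex") {
    for (p in patterns) {
      ok <- tryCatch({ grepl(p, ""); TRUE }, error = function(e) FALSE,
                     warning = function(w) FALSE)
      if (!ok) stop("invalid regex pattern: ", p, call. = FALSE)
    }
  }
  structure(list(mode = mode, patterns = patterns, match_field = match_field,
                 case_sensitive = isTRUE(case_sensitive)),
            class = "series_filter")
}

#' Does an instance match a series filter?
#'
#' Pure predicate: `TRUE` iff any pattern matches the record's match field
#' under the filter's mode and case policy. A record whose match field is
#' absent never matches.
#'
#' @param record A [dicom_instance_record()].
#' @param filter A [series_filter()].
#' @return Logical scalar.
#' @export
match_series <- function(record, filter) {
  stopifnot(inherits(filter, "series_filter"))
  field <- switch(filter$match_field,
                  series_description = record$series_description,
                  series_number = as.character(ds_get(record$dataset, "SeriesNumber")),
                  modality = record$modality)
  if (is.null(field) || length(field) == 0L || is.na(field)) return(FALSE)
  subject <- if (filter$case_sensitive) field else toupper(field)
  patterns <- if (filter$case_sensitive) filter$patterns else toupper(filter$patterns)
  any(vapply(patterns, function(p) {
    switch(filter$mode,
           substring = grepl(p, subject, fixed = TRUE),
           exact = identical(p, subject),
           regex = grepl(p, subject, ignore.case = !filter$case_sensitive))
  }, TRUE))
}

#' Create a router
#'
#' Holds the mutable routing state: per-series receive buffers, the session
#' [uid_map()], and routing reports. Timestamps are supplied by the caller
#' from a monotonic clock, so completion detection is immune to wall-clock
#' jumps and fully testable.
#'
#' @param filter A [series_filter()].
#' @param profile An [anonymization_profile()].
#' @param timeout_seconds Quiet period after the last received instance of a
#'   series before it is considered complete (default 30).
#' @param retries,retry_delay Peer-failure policy for dispatch: number of
#'   attempts per object and fixed spacing (seconds) between them.
#' @return A `dicom_router` (environment-backed).
#' @export
dicom_router <- function(filter, profile = default_anonymization_profile(),
                         timeout_seconds = 30, retries = 3L, retry_delay = 5) {
  stopifnot(inherits(filter, "series_filter"),
            inherits(profile, "anonymization_profile"),
            timeout_seconds > 0)
  e <- new.env(parent = emptyenv())
  e$filter <- filter
  e$profile <- profile
  e$map <- uid_map()
  e$timeout_seconds <- timeout_seconds
  e$retries <- as.integer(retries)
  e$retry_delay <- retry_delay
  e$buffers <- list()       # keyed by anonymized series UID
  e$reports <- list()       # one row per series, updated across stages
  e$known_series <- character()  # anonymized series UIDs ever dispatched
  class(e) <- "dicom_router"
  e
}

.report_row <- function(series_uid, received = 0L, archive = 0L, processor = 0L,
                        filtered_out = FALSE, first_receipt = NA_real_,
                        completed = NA_real_, dispatched = NA_real_) {
  tibble::tibble(series_instance_uid = series_uid,
                 instances_received = as.integer(received),
                 instances_forwarded_archive = as.integer(archive),
                 instances_forwarded_processor = as.integer(processor),
                 filtered_out = filtered_out,
                 t_first_receipt = first_receipt,
                 t_completed = completed,
                 t_dispatched = dispatched)
}

#' Ingest one C-STORE'd object into the router
#'
#' Non-matching series are acknowledged with success but only recorded as
#' filtered (silent acceptance keeps the sending PACS free of errors in a
#' shadow deployment). Matching instances are anonymized and appended to
#' their series buffer; re-sending the same SOP instance overwrites the
#' stored copy.
#'
#' @param router A [dicom_router()].
#' @param obj A `dcm_dataset`, [dicom_instance_record()], file path, or raw
#'   vector holding a Part-10 object.
#' @param now Monotonic timestamp in seconds.
#' @return DIMSE status code: `0x0000` on success, `0xC000` for an
#'   undecodable dataset.
#' @export
router_ingest <- function(router, obj, now) {
  stopifnot(inherits(router, "dicom_router"))
  record <- tryCatch({
    if (inherits(obj, "dicom_instance_record")) obj
    else if (inherits(obj, "dcm_dataset")) dicom_instance_record(obj)
    else dicom_instance_record(dcm_read(obj))
  }, error = function(e) NULL)
  if (is.null(record)) return(DIMSE_CANNOT_UNDERSTAND)

  if (!match_series(record, router$filter)) {
    orig <- record$series_instance_uid
    if (is.null(router$reports[[orig]])) {
      router$reports[[orig]] <- .report_row(orig, filtered_out = TRUE,
                                            first_receipt = now)
    }
    router$reports[[orig]]$instances_received <-
      router$reports[[orig]]$instances_received + 1L
    return(DIMSE_SUCCESS)
  }

  anon <- anonymize_instance(record, router$profile, router$map)
  uid <- anon$series_instance_uid
  buf <- router$buffers[[uid]]
  if (is.null(buf)) {
    buf <- list(series_instance_uid = uid,
                original_series_uid = record$series_instance_uid,
                instances = list(),
                last_receipt_time = now,
                first_receipt_time = now,
                state = "accumulating")
  }
  buf$instances[[anon$sop_instance_uid]] <- anon
  buf$last_receipt_time <- now
  buf$state <- "accumulating"
  router$buffers[[uid]] <- buf
  if (is.null(router$reports[[uid]])) {
    router$reports[[uid]] <- .report_row(uid, first_receipt = now)
  }
  router$reports[[uid]]$instances_received <- length(buf$instances)
  DIMSE_SUCCESS
}

#' Collect series whose receive timeout has elapsed
#'
#' Returns every accumulating buffer with `now - last_receipt_time >=
#' timeout`, transitioning each to `complete`; buffers still receiving are
#' untouched. The returned list is ordered by last receipt time ascending.
#'
#' @param router A [dicom_router()].
#' @param now Monotonic timestamp, seconds.
#' @param timeout Override of the router's timeout (seconds).
#' @return List of completed series buffers.
#' @export
router_sweep_completions <- function(router, now, timeout = router$timeout_seconds) {
  stopifnot(inherits(router, "dicom_router"), timeout > 0)
  ready <- list()
  for (uid in names(router$buffers)) {
    buf <- router$buffers[[uid]]
    if (identical(buf$state, "accumulating") &&
        now - buf$last_receipt_time >= timeout) {
      buf$state <- "complete"
      router$buffers[[uid]] <- buf
      router$reports[[uid]]$t_completed <- now
      ready[[length(ready) + 1L]] <- buf
    }
  }
  if (length(ready) > 1L) {
    ready <- ready[order(vapply(ready, function(b) b$last_receipt_time, 0))]
  }
  ready
}

.store_with_retry <- function(router, peer, ds) {
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    ok <- tryCatch({ peer$store(ds); TRUE }, error = function(e) FALSE)
    if (ok) return(TRUE)
    if (attempt >= router$retries) return(FALSE)
    if (router$retry_delay > 0) Sys.sleep(router$retry_delay)
  }
}

#' Dispatch a completed series to the archive and processing peers
#'
#' Every buffered (anonymized) instance is stored to both peers; the buffer
#' then transitions to `dispatched`. Dispatch of distinct series is
#' serialized by construction (single-threaded callers). On peer failure
#' after the retry policy, a transfer error naming the peer is raised, the
#' buffer remains `complete` for retry, and the partial counts stay in the
#' routing report.
#'
#' @param router A [dicom_router()].
#' @param buffer A buffer returned by [router_sweep_completions()].
#' @param archive,processor Peers (see [dir_peer()]).
#' @param now Monotonic timestamp recorded in the report.
#' @return The updated routing report row (tibble).
#' @export
router_dispatch <- function(router, buffer, archive, processor, now = NA_real_) {
  stopifnot(inherits(router, "dicom_router"))
  uid <- buffer$series_instance_uid
  buffer <- router$buffers[[uid]]
  if (!identical(buffer$state, "complete")) {
    stop(errorCondition(sprintf("series %s is not complete (state: %s)", uid, buffer$state),
                        class = c("ctqv_precondition_error", "ctqv_error")))
  }
  if (!length(buffer$instances)) {
    stop(errorCondition("series buffer is complete but empty",
                        class = c("ctqv_precondition_error", "ctqv_error")))
  }
  ordered <- sort_series(unname(buffer$instances))
  n_archive <- 0L; n_processor <- 0L
  failed_peer <- NULL
  for (rec in ordered) {
    if (!.store_with_retry(router, archive, rec$dataset)) { failed_peer <- archive; break }
    n_archive <- n_archive + 1L
  }
  if (is.null(failed_peer)) {
    for (rec in ordered) {
      if (!.store_with_retry(router, processor, rec$dataset)) { failed_peer <- processor; break }
      n_processor <- n_processor + 1L
    }
  }
  rep <- router$reports[[uid]]
  rep$instances_forwarded_archive <- n_archive
  rep$instances_forwarded_processor <- n_processor
  if (is.null(failed_peer)) {
    rep$t_dispatched <- now
    buffer$state <- "dispatched"
    router$buffers[[uid]] <- buffer
    router$known_series <- union(router$known_series, uid)
  }
  router$reports[[uid]] <- rep
  if (!is.null(failed_peer)) {
    stop(errorCondition(
      sprintf("transfer to peer %s failed for series %s", failed_peer$ae_title, uid),
      class = c("ctqv_transfer_error", "ctqv_error"), report = rep))
  }
  rep
}

#' Handle a SEG object returned by the processing host
#'
#' Decodes the SEG, computes per-segment volumetry from its pixel data,
#' builds the SR measurement document, and stores SEG then SR to the
#' archive. A SEG referencing a series this router never dispatched is
#' forwarded with a warning (the archive resolves linkage); a non-SEG
#' object is rejected with an error status.
#'
#' @param router A [dicom_router()].
#' @param seg_object A SEG `dcm_dataset`, path or raw Part-10.
#' @param archive Archive peer.
#' @return A list: `status` (DIMSE code), `volumes` (tibble or NULL),
#'   `seg`, `sr` (datasets or NULL).
#' @export
router_handle_returned_seg <- function(router, seg_object, archive) {
  stopifnot(inherits(router, "dicom_router"))
  seg <- tryCatch({
    if (inherits(seg_object, "dcm_dataset")) seg_object else dcm_read(seg_object)
  }, error = function(e) NULL)
  if (is.null(seg) ||
      !identical(ds_get(seg, "SOPClassUID"), DCM_UID$segmentation_storage)) {
    return(list(status = DIMSE_CANNOT_UNDERSTAND, volumes = NULL, seg = NULL, sr = NULL))
  }
  decoded <- decode_seg(seg)
  if (!is.na(decoded$referenced_series_uid) &&
      !(decoded$referenced_series_uid %in% router$known_series)) {
    warning("SEG references series ", decoded$referenced_series_uid,
            " unknown to this router; forwarding anyway", call. = FALSE)
  }
  volumes <- compute_volumes(decoded$labels, decoded$descriptors)
  sr <- build_structured_report(
    volumes,
    seg_reference = c(ds_get(seg, "SOPClassUID"), ds_get(seg, "SOPInstanceUID")),
    source_study_uid = ds_get(seg, "StudyInstanceUID"),
    source_series_uid = decoded$referenced_series_uid)
  archive$store(seg)
  archive$store(sr)
  list(status = DIMSE_SUCCESS, volumes = volumes, seg = seg, sr = sr)
}

#' Routing reports accumulated by a router
#' @param router A [dicom_router()].
#' @return A tibble, one row per series seen.
#' @export
router_reports <- function(router) {
  stopifnot(inherits(router, "dicom_router"))
  if (!length(router$reports)) return(.report_row(character(0)))
  do.call(rbind, unname(router$reports))
}

#' @export
print.dicom_router <- function(x, ...) {
  cat(sprintf("<dicom_router: %d buffered series, timeout %gs>\n",
              length(x$buffers), x$timeout_seconds))
  invisible(x)
}

# ---- stub peers ------------------------------------------------------------

#' Directory-backed storage peer
#'
#' A function-call C-STORE peer that persists every received object as a
#' Part-10 file. Stands in for the external archive / processing host in
#' tests and local deployments.
#'
#' @param ae_title Peer AE title.
#' @param dir Storage directory (created if needed).
#' @return A peer: list with `ae_title`, `dir`, `store(ds)`, `echo()`,
#'   `stored_files()`.
#' @export
dir_peer <- function(ae_title, dir = tempfile(paste0("peer_", ae_title, "_"))) {
  addr <- node_address(ae_title)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counter <- local({ i <- 0L; function() { i <<- i + 1L; i } })
  list(
    ae_title = addr$ae_title,
    dir = dir,
    store = function(ds) {
      sop <- ds_get(ds, "SOPInstanceUID")
      path <- file.path(dir, paste0(sop, ".dcm"))
      dcm_write(ds, path)
      invisible(DIMSE_SUCCESS)
    },
    echo = function() DIMSE_SUCCESS,
    stored_files = function() list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  )
}

#' A peer that refuses every store (for failure-path tests)
#' @param ae_title Peer AE title.
#' @return A peer whose `store()` always fails.
#' @export
unreachable_peer <- function(ae_title) {
  addr <- node_address(ae_title)
  list(ae_title = addr$ae_title,
       dir = NULL,
       store = function(ds) stop("association rejected by ", addr$ae_title, call. = FALSE),
       echo = function() stop("peer unreachable", call. = FALSE),
       stored_files = function() character(0))
}
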