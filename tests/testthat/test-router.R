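make_router <- function(timeout = 30) {
  dicom_router(series_filter("PV"), default_anonymization_profile(),
               timeout_seconds = timeout, retry_delay = 0)
}

test_that("ingest buffers matching instances, acknowledges and marks filtered ones", {
  set.seed(41)
  router <- make_router()
  status <- router_ingest(router, tiny_ct_dataset("1.2.840.99.10", "1.2.840.99.10.1"), now = 1)
  expect_identical(status, DIMSE_SUCCESS)
  expect_length(router$buffers, 1)
  expect_length(router$buffers[[1]]$instances, 1)

  # duplicate re-send is idempotent
  router_ingest(router, tiny_ct_dataset("1.2.840.99.10", "1.2.840.99.10.1"), now = 2)
  expect_length(router$buffers[[1]]$instances, 1)

  # non-matching series: success status, nothing buffered, marked filtered
  status <- router_ingest(router,
                          tiny_ct_dataset("1.2.840.99.11", "1.2.840.99.11.1",
                                          series_description = "ARTERIAL 3MM"),
                          now = 3)
  expect_identical(status, DIMSE_SUCCESS)
  expect_length(router$buffers, 1)
  reports <- router_reports(router)
  expect_true(reports$filtered_out[reports$series_instance_uid == "1.2.840.99.11"])

  # undecodable payload -> error status, nothing buffered
  bad <- tempfile(fileext = ".dcm")
  writeBin(as.raw(1:64), bad)
  expect_identical(router_ingest(router, bad, now = 4), DIMSE_CANNOT_UNDERSTAND)
  expect_length(router$buffers, 1)
})

test_that("buffered instances are anonymized on ingest", {
  set.seed(42)
  router <- make_router()
  router_ingest(router, tiny_ct_dataset("1.2.840.99.12", "1.2.840.99.12.1"), now = 1)
  buf <- router$buffers[[1]]
  inst <- buf$instances[[1]]
  expect_false(ds_has(inst$dataset, "PatientName"))
  expect_false(identical(inst$series_instance_uid, "1.2.840.99.12"))
  expect_identical(buf$original_series_uid, "1.2.840.99.12")
})

test_that("sweep returns exactly the series whose quiet period reached the timeout", {
  set.seed(43)
  router <- make_router(timeout = 30)
  router_ingest(router, tiny_ct_dataset("1.2.840.99.13", "1.2.840.99.13.1"), now = 0)
  expect_length(router_sweep_completions(router, now = 29), 0)
  ready <- router_sweep_completions(router, now = 31)
  expect_length(ready, 1)
  expect_identical(ready[[1]]$state, "complete")
  # a completed buffer is not returned again
  expect_length(router_sweep_completions(router, now = 32), 0)
})

test_that("interleaved series complete independently (stale vs fresh)", {
  set.seed(44)
  router <- make_router(timeout = 30)
  router_ingest(router, tiny_ct_dataset("1.2.840.99.14", "1.2.840.99.14.1"), now = 0)
  router_ingest(router, tiny_ct_dataset("1.2.840.99.15", "1.2.840.99.15.1"), now = 35)
  ready <- router_sweep_completions(router, now = 40)   # A stale 40s, B fresh 5s
  expect_length(ready, 1)
  expect_identical(ready[[1]]$original_series_uid, "1.2.840.99.14")
  # brute-force re-evaluation of the timeout predicate over both buffers
  for (buf in router$buffers) {
    should_complete <- 40 - buf$last_receipt_time >= 30
    expect_identical(identical(buf$state, "complete"), should_complete)
  }
})

test_that("dispatch conserves instances to both peers and transitions the buffer", {
  set.seed(45)
  router <- make_router()
  for (i in 1:5) {
    router_ingest(router, tiny_ct_dataset("1.2.840.99.16", paste0("1.2.840.99.16.", i),
                                          z = 3 * i, instance_number = i), now = i)
  }
  ready <- router_sweep_completions(router, now = 100)
  archive <- dir_peer("ARCHIVE")
  processor <- dir_peer("DLHOST")
  rep <- router_dispatch(router, ready[[1]], archive, processor, now = 101)
  expect_identical(rep$instances_received, 5L)
  expect_identical(rep$instances_forwarded_archive, 5L)
  expect_identical(rep$instances_forwarded_processor, 5L)
  expect_length(archive$stored_files(), 5)
  expect_length(processor$stored_files(), 5)
  expect_identical(router$buffers[[1]]$state, "dispatched")
})

test_that("peer failure raises a transfer error naming the peer and leaves the buffer retryable", {
  set.seed(46)
  router <- make_router()
  router_ingest(router, tiny_ct_dataset("1.2.840.99.17", "1.2.840.99.17.1"), now = 0)
  ready <- router_sweep_completions(router, now = 100)
  archive <- unreachable_peer("DEADARCHIVE")
  processor <- dir_peer("DLHOST")
  err <- tryCatch(router_dispatch(router, ready[[1]], archive, processor),
                  ctqv_transfer_error = function(e) e)
  expect_s3_class(err, "ctqv_transfer_error")
  expect_match(conditionMessage(err), "DEADARCHIVE")
  expect_identical(err$report$instances_forwarded_archive, 0L)
  expect_identical(router$buffers[[1]]$state, "complete")
  # retry against a healthy archive succeeds
  rep <- router_dispatch(router, ready[[1]], dir_peer("ARCHIVE"), processor)
  expect_identical(rep$instances_forwarded_archive, 1L)
})

test_that("an empty complete buffer violates the dispatch precondition", {
  router <- make_router()
  fake <- list(series_instance_uid = "1.2.3", instances = list(), state = "complete")
  router$buffers[["1.2.3"]] <- fake
  router$reports[["1.2.3"]] <- ctqv:::.report_row("1.2.3")
  expect_error(router_dispatch(router, fake, dir_peer("A"), dir_peer("B")),
               class = "ctqv_precondition_error")
})

test_that("a returned SEG yields SEG then SR at the archive with matching volumetry", {
  set.seed(47)
  spec <- small_lesion_spec(shape = c(24L, 24L, 8L), semi_axes = c(8, 7, 9))
  g <- generate_series(spec, tempfile())
  seg <- encode_seg(g$truth, list(segment_descriptor(1L, "pelvic hematoma")),
                    sort_series(g$records))
  router <- make_router()
  router$known_series <- g$series_instance_uid
  archive <- dir_peer("ARCHIVE")
  res <- router_handle_returned_seg(router, seg, archive)
  expect_identical(res$status, DIMSE_SUCCESS)
  expect_length(archive$stored_files(), 2)
  direct <- compute_volumes(g$truth, list(segment_descriptor(1L, "pelvic hematoma")))
  expect_identical(res$volumes$volume_ml, direct$volume_ml)
  m <- sr_measurements(res$sr)
  expect_identical(m$volume_ml, direct$volume_ml)
  expect_identical(attr(m, "seg_sop_instance_uid"), ds_get(seg, "SOPInstanceUID"))
})

test_that("a SEG for an unknown series is forwarded with a warning; non-SEG is rejected", {
  set.seed(48)
  spec <- small_lesion_spec(shape = c(16L, 16L, 6L), semi_axes = c(6, 6, 7))
  g <- generate_series(spec, tempfile())
  seg <- encode_seg(g$truth, list(segment_descriptor(1L, "lesion")), sort_series(g$records))
  router <- make_router()
  archive <- dir_peer("ARCHIVE")
  expect_warning(res <- router_handle_returned_seg(router, seg, archive), "unknown")
  expect_identical(res$status, DIMSE_SUCCESS)
  expect_length(archive$stored_files(), 2)

  ct <- tiny_ct_dataset("1.2.840.99.18", "1.2.840.99.18.1")
  res2 <- router_handle_returned_seg(router, ct, archive)
  expect_identical(res2$status, DIMSE_CANNOT_UNDERSTAND)
  expect_length(archive$stored_files(), 2)
})

test_that("every received instance is either forwarded to both peers or marked filtered", {
  set.seed(49)
  router <- make_router()
  n_match <- 4L; n_nomatch <- 3L
  for (i in seq_len(n_match)) {
    router_ingest(router, tiny_ct_dataset("1.2.840.99.19", paste0("1.2.840.99.19.", i),
                                          z = 3 * i, instance_number = i), now = i)
  }
  for (i in seq_len(n_nomatch)) {
    router_ingest(router, tiny_ct_dataset("1.2.840.99.20", paste0("1.2.840.99.20.", i),
                                          series_description = "SCOUT"), now = i)
  }
  ready <- router_sweep_completions(router, now = 1000)
  archive <- dir_peer("ARCHIVE"); processor <- dir_peer("DLHOST")
  for (buf in ready) router_dispatch(router, buf, archive, processor)
  reports <- router_reports(router)
  expect_identical(sum(reports$instances_received), n_match + n_nomatch)
  forwarded <- reports[!reports$filtered_out, ]
  expect_identical(forwarded$instances_forwarded_archive, forwarded$instances_received)
  expect_identical(forwarded$instances_forwarded_processor, forwarded$instances_received)
  expect_identical(sum(reports$filtered_out), 1L)
  expect_true(all(reports$instances_forwarded_archive[reports$filtered_out] == 0L))
})
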