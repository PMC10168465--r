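# YAML pipeline configuration with a strict, documented schema: unknown
# keys are rejected by name so a typo ("timout") cannot silently disable a
# setting at a clinical site.

.cfg_error <- function(...) {
  stop(errorCondition(sprintf(...), class = c("ctqv_config_error", "ctqv_error")))
}

.check_keys <- function(x, known, where) {
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    .cfg_error("unknown config key(s) in %s: %s", where, paste(unknown, collapse = ", "))
  }
}

.cfg_node <- function(x, where) {
  .check_keys(x, c("ae_title", "host", "port"), where)
  for (k in c("ae_title", "host", "port")) {
    if (is.null(x[[k]])) .cfg_error("missing required key %s.%s", where, k)
  }
  tryCatch(node_address(x$ae_title, x$host, x$port),
           error = function(e) .cfg_error("%s: %s", where, conditionMessage(e)))
}

.cfg_filter <- function(x) {
  .check_keys(x, c("mode", "patterns", "match_field", "case_sensitive"), "series_filter")
  if (is.null(x$patterns)) .cfg_error("missing required key series_filter.patterns")
  tryCatch(series_filter(patterns = unlist(x$patterns),
                         mode = x$mode %||% "substring",
                         match_field = x$match_field %||% "series_description",
                         case_sensitive = x$case_sensitive %||% FALSE),
           error = function(e) .cfg_error("series_filter: %s", conditionMessage(e)))
}

.cfg_backend <- function(x) {
  .check_keys(x, c("kind", "hu_low", "hu_high", "min_component_voxels",
                   "keep_largest_only", "command", "timeout_seconds"), "backend")
  args <- list(kind = x$kind %||% "threshold_stub")
  for (k in c("hu_low", "hu_high", "min_component_voxels", "keep_largest_only",
              "command", "timeout_seconds")) {
    if (!is.null(x[[k]])) args[[k]] <- x[[k]]
  }
  tryCatch(do.call(backend_spec, args),
           error = function(e) .cfg_error("backend: %s", conditionMessage(e)))
}

.cfg_anonymization <- function(x) {
  if (is.null(x)) return(default_anonymization_profile())
  .check_keys(x, c("remove_tags", "replace_tags", "remap_uids", "coarsen_dates",
                   "strip_private"), "anonymization")
  base <- default_anonymization_profile()
  tryCatch(anonymization_profile(
    remove_tags = if (is.null(x$remove_tags)) .dcm_keyword_by_tag[base$remove_tags] else unlist(x$remove_tags),
    replace_tags = if (is.null(x$replace_tags)) {
      stats::setNames(base$replace_tags, .dcm_keyword_by_tag[names(base$replace_tags)])
    } else x$replace_tags,
    remap_uids = x$remap_uids %||% base$remap_uids,
    coarsen_dates = x$coarsen_dates %||% base$coarsen_dates,
    strip_private = x$strip_private %||% base$strip_private
  ), error = function(e) .cfg_error("anonymization: %s", conditionMessage(e)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.CFG_TOP_KEYS <- c("router", "archive", "processor", "series_filter",
                   "timeout_seconds", "anonymization", "backend",
                   "segment_attributes_path", "spool_dir", "log_level")

#' Load and validate a pipeline configuration
#'
#' Required keys: `router`, `archive`, `processor` (each with `ae_title`,
#' `host`, `port`), `series_filter` (`patterns` at minimum),
#' `segment_attributes_path`. Optional: `backend` (default: threshold stub),
#' `anonymization` (default profile), `timeout_seconds` (default 30, the
#' series-completion quiet period), `spool_dir`, `log_level`. Unknown keys
#' are rejected with the offending key named; the three AE titles must be
#' pairwise distinct.
#'
#' @param path Path to the YAML file.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) .cfg_error("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  .check_keys(raw, .CFG_TOP_KEYS, "top level")
  for (k in c("router", "archive", "processor", "series_filter", "segment_attributes_path")) {
    if (is.null(raw[[k]])) .cfg_error("missing required key %s", k)
  }
  router <- .cfg_node(raw$router, "router")
  archive <- .cfg_node(raw$archive, "archive")
  processor <- .cfg_node(raw$processor, "processor")
  aes <- c(router = router$ae_title, archive = archive$ae_title,
           processor = processor$ae_title)
  dup <- aes[duplicated(aes) | duplicated(aes, fromLast = TRUE)]
  if (length(dup)) {
    .cfg_error("AE titles must be pairwise distinct: %s share %s",
               paste(names(dup), collapse = " and "), dQuote(dup[1]))
  }
  timeout <- raw$timeout_seconds %||% 30
  if (!is.numeric(timeout) || timeout <= 0) .cfg_error("timeout_seconds must be > 0")
  structure(list(
    router = router, archive = archive, processor = processor,
    series_filter = .cfg_filter(raw$series_filter),
    timeout_seconds = as.numeric(timeout),
    anonymization = .cfg_anonymization(raw$anonymization),
    backend = .cfg_backend(raw$backend %||% list()),
    segment_attributes_path = raw$segment_attributes_path,
    spool_dir = raw$spool_dir,
    log_level = raw$log_level %||% "info"
  ), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  router/archive/processor AE: %s / %s / %s\n",
              x$router$ae_title, x$archive$ae_title, x$processor$ae_title))
  cat(sprintf("  filter: %s on %s (%s)\n",
              paste(x$series_filter$patterns, collapse = ", "),
              x$series_filter$match_field, x$series_filter$mode))
  cat(sprintf("  timeout: %gs; backend: %s\n", x$timeout_seconds, x$backend$kind))
  invisible(x)
}
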