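# UID generation and the session UID map used by the anonymizer.

.UID_ROOT <- "2.25."

#' Validate a DICOM UID
#'
#' A valid UID is non-empty, at most 64 characters, and consists of
#' dot-separated numeric components without leading zeros (single "0"
#' components allowed).
#'
#' @param uid Character scalar.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_uid <- function(uid) {
  if (!is.character(uid) || length(uid) != 1L || is.na(uid)) return(FALSE)
  if (nchar(uid) == 0L || nchar(uid) > 64L) return(FALSE)
  grepl("^(0|[1-9][0-9]*)(\\.(0|[1-9][0-9]*))*$", uid)
}

.assert_uid <- function(uid, what = "UID") {
  if (!is_valid_uid(uid)) {
    stop(sprintf("malformed %s: %s", what,
                 if (is.character(uid) && length(uid) == 1L) dQuote(uid) else "<non-string>"),
         call. = FALSE)
  }
  invisible(uid)
}

#' Generate a fresh DICOM UID
#'
#' Draws a 38-digit random integer from the session RNG under the 2.25 UUID
#' arc. Fresh UIDs are used for anonymized identifier trees and for the new
#' SEG/SR series and instances.
#'
#' @return A valid UID string (length <= 44 characters).
#' @export
new_uid <- function() {
  digits <- c(sample(1:9, 1L), sample(0:9, 37L, replace = TRUE))
  paste0(.UID_ROOT, paste(digits, collapse = ""))
}

#' Create a session UID map
#'
#' The map records original -> anonymized UID pairs so that every object in
#' one pipeline session keeps a consistent, linked identifier tree (study,
#' series, instance, frame of reference) after de-identification.
#'
#' @return A `uid_map` (environment-backed, updated in place).
#' @export
uid_map <- function() {
  structure(list(fwd = new.env(parent = emptyenv()),
                 rev = new.env(parent = emptyenv())),
            class = "uid_map")
}

#' Remap a UID through a session map
#'
#' Idempotent and injective: the first lookup of an original UID creates a
#' fresh anonymized UID (never equal to the original); later lookups return
#' the identical value.
#'
#' @param original A valid UID string.
#' @param map A [uid_map()].
#' @return The anonymized UID.
#' @export
remap_uid <- function(original, map) {
  stopifnot(inherits(map, "uid_map"))
  .assert_uid(original)
  existing <- map$fwd[[original]]
  if (!is.null(existing)) return(existing)
  repeat {
    candidate <- new_uid()
    if (candidate != original && is.null(map$rev[[candidate]])) break
  }
  assign(original, candidate, envir = map$fwd)
  assign(candidate, original, envir = map$rev)
  candidate
}

#' @export
print.uid_map <- function(x, ...) {
  cat(sprintf("<uid_map: %d UIDs remapped>\n", length(ls(x$fwd))))
  invisible(x)
}
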