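# Minimal DICOM Part-10 codec: explicit and implicit VR little endian,
# nested sequences with defined or undefined lengths. Covers the CT Image,
# Segmentation and Comprehensive SR objects the pipeline produces and
# consumes. Datasets are named lists of elements keyed by "GGGGEEEE" tag;
# an element is list(vr, value). Value conventions:
#   string VRs -> character vector (one entry per value-multiplicity item)
#   IS/DS      -> numeric
#   US/SS/UL   -> integer/numeric vector
#   OB/OW/UN   -> raw
#   SQ         -> list of datasets

.STRING_VRS <- c("AE", "AS", "CS", "DA", "DT", "LO", "LT", "PN", "SH", "ST", "TM", "UI", "UT")

#' Create an empty DICOM dataset
#' @return An empty `dcm_dataset`.
#' @export
ds_new <- function() structure(list(), class = "dcm_dataset")

#' Set an attribute in a DICOM dataset
#'
#' @param ds A `dcm_dataset`.
#' @param keyword Attribute keyword or 8-char hex tag.
#' @param value Value using the codec's R-side conventions (see `dcm_read()`).
#' @param vr Override the dictionary VR (needed only for private tags).
#' @return The modified dataset.
#' @export
ds_set <- function(ds, keyword, value, vr = NULL) {
  tag <- dcm_tag(keyword)
  if (is.null(vr)) vr <- dcm_vr_of(tag)
  ds[[tag]] <- list(vr = vr, value = value)
  ds
}

#' @export
ds_get <- function(ds, keyword, default = NULL) {
  el <- ds[[dcm_tag(keyword)]]
  if (is.null(el)) default else el$value
}

#' @export
ds_has <- function(ds, keyword) !is.null(ds[[dcm_tag(keyword)]])

#' @export
ds_del <- function(ds, keyword) {
  ds[[dcm_tag(keyword)]] <- NULL
  ds
}

# ---- byte-level helpers (unsigned little endian via raw arithmetic) --------

.u16_raw <- function(x) {
  x <- as.integer(x)
  as.raw(as.vector(rbind(x %% 256L, x %/% 256L)))
}

.u32_raw <- function(x) {
  x <- as.numeric(x)
  b0 <- x %% 256; x <- x %/% 256
  b1 <- x %% 256; x <- x %/% 256
  b2 <- x %% 256; b3 <- x %/% 256
  as.raw(as.vector(rbind(b0, b1, b2, b3)))
}

.read_u16 <- function(buf, pos) {
  as.integer(buf[pos]) + 256L * as.integer(buf[pos + 1L])
}

.read_u32 <- function(buf, pos) {
  as.numeric(buf[pos]) + 256 * as.numeric(buf[pos + 1L]) +
    65536 * as.numeric(buf[pos + 2L]) + 16777216 * as.numeric(buf[pos + 3L])
}

.pad_even <- function(r, pad) {
  if (length(r) %% 2L == 1L) c(r, pad) else r
}

# ---- value encoding --------------------------------------------------------

.fmt_ds <- function(x) {
  s <- vapply(x, function(v) formatC(v, digits = 10, format = "g"), "")
  # DS values are limited to 16 bytes
  long <- nchar(s) > 16L
  if (any(long)) s[long] <- vapply(x[long], function(v) formatC(v, digits = 8, format = "g"), "")
  s
}

.encode_value <- function(vr, value) {
  if (vr %in% c("OB", "OW", "UN")) {
    r <- as.raw(value)
    return(.pad_even(r, as.raw(0L)))
  }
  if (vr == "US") return(.u16_raw(value))
  if (vr == "SS") {
    x <- as.integer(value)
    x <- ifelse(x < 0L, x + 65536L, x)
    return(.u16_raw(x))
  }
  if (vr == "UL") return(.u32_raw(value))
  if (vr == "FD") return(writeBin(as.numeric(value), raw(), size = 8, endian = "little"))
  if (vr == "DS") value <- .fmt_ds(as.numeric(value))
  if (vr == "IS") value <- as.character(as.integer(value))
  s <- paste(as.character(value), collapse = "\\")
  r <- charToRaw(s)
  .pad_even(r, if (vr == "UI") as.raw(0L) else charToRaw(" "))
}

.encode_element <- function(tag, el, explicit) {
  group <- strtoi(substr(tag, 1, 4), 16L)
  elem <- strtoi(substr(tag, 5, 8), 16L)
  head <- c(.u16_raw(group), .u16_raw(elem))
  vr <- el$vr
  if (vr == "SQ") {
    body <- do.call(c, c(list(raw(0)), lapply(el$value, function(item) {
      content <- .encode_dataset(item, explicit)
      c(.u16_raw(0xFFFE), .u16_raw(0xE000), .u32_raw(length(content)), content)
    })))
    if (explicit) {
      return(c(head, charToRaw("SQ"), as.raw(c(0, 0)), .u32_raw(length(body)), body))
    }
    return(c(head, .u32_raw(length(body)), body))
  }
  body <- .encode_value(vr, el$value)
  if (!explicit) {
    return(c(head, .u32_raw(length(body)), body))
  }
  if (vr %in% c("OB", "OW", "UN", "UT")) {
    c(head, charToRaw(vr), as.raw(c(0, 0)), .u32_raw(length(body)), body)
  } else {
    c(head, charToRaw(vr), .u16_raw(length(body)), body)
  }
}

.encode_dataset <- function(ds, explicit) {
  tags <- sort(names(ds))
  parts <- lapply(tags, function(tag) .encode_element(tag, ds[[tag]], explicit))
  do.call(c, c(list(raw(0)), parts))
}

# ---- Part-10 write ---------------------------------------------------------

CTQV_IMPLEMENTATION_UID <- "2.25.313974278127631485276132841043527836547"

#' Write a dataset as a DICOM Part-10 file
#'
#' File meta information is generated from the dataset's SOPClassUID and
#' SOPInstanceUID; the main dataset is written in explicit VR little endian.
#'
#' @param ds A `dcm_dataset` containing at least SOPClassUID and SOPInstanceUID.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
dcm_write <- function(ds, path) {
  sop_class <- ds_get(ds, "SOPClassUID")
  sop_inst <- ds_get(ds, "SOPInstanceUID")
  if (is.null(sop_class) || is.null(sop_inst)) {
    stop("dataset must carry SOPClassUID and SOPInstanceUID", call. = FALSE)
  }
  # drop any stale group-0002 elements; meta is regenerated
  ds <- ds[!startsWith(names(ds), "0002")]
  class(ds) <- "dcm_dataset"

  meta <- ds_new()
  meta <- ds_set(meta, "FileMetaInformationVersion", as.raw(c(0, 1)))
  meta <- ds_set(meta, "MediaStorageSOPClassUID", sop_class)
  meta <- ds_set(meta, "MediaStorageSOPInstanceUID", sop_inst)
  meta <- ds_set(meta, "TransferSyntaxUID", DCM_UID$explicit_vr_le)
  meta <- ds_set(meta, "ImplementationClassUID", CTQV_IMPLEMENTATION_UID)
  meta <- ds_set(meta, "ImplementationVersionName", "CTQV_0_1")
  meta_body <- .encode_dataset(meta, explicit = TRUE)
  group_len <- c(.u16_raw(2L), .u16_raw(0L), charToRaw("UL"), .u16_raw(4L),
                 .u32_raw(length(meta_body)))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(group_len, con)
  writeBin(meta_body, con)
  writeBin(.encode_dataset(ds, explicit = TRUE), con)
  invisible(path)
}

# ---- value decoding --------------------------------------------------------

.decode_value <- function(vr, buf, pos, len) {
  if (len == 0) {
    if (vr %in% c("OB", "OW", "UN")) return(raw(0))
    if (vr %in% c("DS", "IS")) return(numeric(0))
    if (vr %in% c("US", "SS", "UL")) return(integer(0))
    return(character(0))
  }
  bytes <- buf[pos:(pos + len - 1L)]
  if (vr %in% c("OB", "OW", "UN")) return(bytes)
  if (vr == "US") return(readBin(bytes, integer(), n = len / 2, size = 2, endian = "little", signed = FALSE))
  if (vr == "SS") return(readBin(bytes, integer(), n = len / 2, size = 2, endian = "little", signed = TRUE))
  if (vr == "UL") {
    n <- len / 4
    vapply(seq_len(n), function(i) .read_u32(bytes, 1L + 4L * (i - 1L)), 0)
  } else if (vr == "FD") {
    readBin(bytes, numeric(), n = len / 8, size = 8, endian = "little")
  } else {
    s <- rawToChar(bytes[bytes != as.raw(0L)])
    s <- sub("[ ]+$", "", s)
    vals <- strsplit(s, "\\", fixed = TRUE)[[1]]
    if (length(vals) == 0) vals <- ""
    if (vr %in% c("DS", "IS")) as.numeric(vals) else vals
  }
}

.parse_items <- function(buf, pos, end, explicit) {
  # parse sequence items until `end` (or a sequence delimitation item)
  items <- list()
  while (pos < end) {
    group <- .read_u16(buf, pos); elem <- .read_u16(buf, pos + 2L)
    len <- .read_u32(buf, pos + 4L)
    pos <- pos + 8L
    if (group == 0xFFFE && elem == 0xE0DD) break   # sequence delimiter
    if (!(group == 0xFFFE && elem == 0xE000)) {
      stop("malformed sequence item at offset ", pos - 8L, call. = FALSE)
    }
    if (len == 4294967295) {                       # undefined-length item
      parsed <- .parse_dataset(buf, pos, end, explicit, stop_at_item_delim = TRUE)
      items[[length(items) + 1L]] <- parsed$ds
      pos <- parsed$pos
    } else {
      parsed <- .parse_dataset(buf, pos, pos + len, explicit, stop_at_item_delim = FALSE)
      items[[length(items) + 1L]] <- parsed$ds
      pos <- pos + len
    }
  }
  list(items = items, pos = pos)
}

.parse_dataset <- function(buf, pos, end, explicit, stop_at_item_delim = FALSE) {
  ds <- list()
  while (pos < end) {
    group <- .read_u16(buf, pos); elem <- .read_u16(buf, pos + 2L)
    if (stop_at_item_delim && group == 0xFFFE && elem == 0xE00D) {
      pos <- pos + 8L
      break
    }
    tag <- sprintf("%04X%04X", group, elem)
    pos <- pos + 4L
    if (explicit) {
      vr <- rawToChar(buf[pos:(pos + 1L)])
      if (vr %in% c("OB", "OW", "OF", "SQ", "UN", "UT")) {
        len <- .read_u32(buf, pos + 4L)
        pos <- pos + 8L
      } else {
        len <- .read_u16(buf, pos + 2L)
        pos <- pos + 4L
      }
    } else {
      vr <- dcm_vr_of(tag)
      len <- .read_u32(buf, pos)
      pos <- pos + 4L
    }
    if (vr == "SQ" || (vr == "UN" && len == 4294967295)) {
      if (len == 4294967295) {
        parsed <- .parse_items(buf, pos, end, explicit)
      } else {
        parsed <- .parse_items(buf, pos, pos + len, explicit)
        parsed$pos <- pos + len
      }
      ds[[tag]] <- list(vr = "SQ", value = parsed$items)
      pos <- parsed$pos
    } else {
      ds[[tag]] <- list(vr = vr, value = .decode_value(vr, buf, pos, len))
      pos <- pos + len
    }
  }
  list(ds = structure(ds, class = "dcm_dataset"), pos = pos)
}

#' Read a DICOM Part-10 file
#'
#' Supports explicit and implicit VR little endian transfer syntaxes.
#' File meta (group 0002) elements are returned as part of the dataset.
#'
#' @param path Path to a Part-10 file, or a raw vector holding one.
#' @return A `dcm_dataset`.
#' @export
dcm_read <- function(path) {
  buf <- if (is.raw(path)) path else readBin(path, raw(), n = file.size(path))
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM") {
    stop("not a DICOM Part-10 file", call. = FALSE)
  }
  pos <- 133L
  # file meta group is always explicit VR LE; first element is the group length
  group <- .read_u16(buf, pos); elem <- .read_u16(buf, pos + 2L)
  if (group != 2L || elem != 0L) stop("missing file meta group length", call. = FALSE)
  meta_len <- .read_u32(buf, pos + 8L)
  pos <- pos + 12L
  meta <- .parse_dataset(buf, pos, pos + meta_len, explicit = TRUE)
  pos <- pos + meta_len
  ts <- ds_get(meta$ds, "TransferSyntaxUID", DCM_UID$explicit_vr_le)
  explicit <- !identical(ts, DCM_UID$implicit_vr_le)
  main <- .parse_dataset(buf, pos, length(buf) + 1L, explicit = explicit)
  out <- c(meta$ds, main$ds)
  structure(out, class = "dcm_dataset")
}

# ---- small shared builders -------------------------------------------------

#' Build a coded-concept sequence item
#' @param value,scheme,meaning Code value, coding scheme designator, meaning.
#' @return A `dcm_dataset` item for a code sequence.
#' @export
dcm_code_item <- function(value, scheme, meaning) {
  ds <- ds_new()
  ds <- ds_set(ds, "CodeValue", value)
  ds <- ds_set(ds, "CodingSchemeDesignator", scheme)
  ds_set(ds, "CodeMeaning", meaning)
}

.code_from_item <- function(item) {
  c(ds_get(item, "CodeValue"), ds_get(item, "CodingSchemeDesignator"),
    ds_get(item, "CodeMeaning"))
}

#' Pack a logical vector into DICOM 1-bit pixel data
#'
#' Bits are packed least-significant-bit first within each byte, continuing
#' across frame boundaries without padding, as the standard requires for
#' binary segmentations.
#' @keywords internal
pack_bits <- function(bits) {
  n <- length(bits)
  pad <- (8L - n %% 8L) %% 8L
  packBits(c(bits, rep(FALSE, pad)), type = "raw")
}

#' @keywords internal
unpack_bits <- function(bytes, n) {
  as.logical(rawToBits(bytes))[seq_len(n)]
}
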