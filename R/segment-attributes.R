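# dcmqi-compatible segment-attributes JSON: the small metadata file that
# gives each label in the mask its clinical meaning (coded category/type),
# display color and algorithm identification for SEG encoding.

.SEGATTR_KNOWN_TOP <- c("BodyPartExamined", "SegmentAttributes",
                        "ContentCreatorName", "SeriesDescription",
                        "SeriesNumber", "InstanceNumber", "ClinicalTrialSeriesID",
                        "ClinicalTrialTimePointID", "ClinicalTrialCoordinatingCenterName")
.SEGATTR_KNOWN_SEG <- c("labelID", "SegmentLabel", "SegmentDescription",
                        "SegmentAlgorithmType", "SegmentAlgorithmName",
                        "SegmentedPropertyCategoryCodeSequence",
                        "SegmentedPropertyTypeCodeSequence",
                        "SegmentedPropertyTypeModifierCodeSequence",
                        "AnatomicRegionSequence", "recommendedDisplayRGBValue")

.code_from_json <- function(x, default) {
  if (is.null(x)) return(default)
  c(x$CodeValue, x$CodingSchemeDesignator, x$CodeMeaning)
}

#' Read a dcmqi-style segment-attributes JSON file
#'
#' Accepts the dcmqi dialect: a top-level `SegmentAttributes` array (flat,
#' or nested one level as dcmqi writes it), each entry carrying `labelID`,
#' `SegmentLabel`, `SegmentAlgorithmType`, `SegmentAlgorithmName`, coded
#' category/type sequences and `recommendedDisplayRGBValue`. Unknown keys
#' are ignored with a warning.
#'
#' @param path Path to the JSON file.
#' @return A list of [segment_descriptor()].
#' @export
read_segment_attributes <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  unknown <- setdiff(names(doc), .SEGATTR_KNOWN_TOP)
  if (length(unknown)) {
    warning("ignoring unknown segment-attribute key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  segs <- doc$SegmentAttributes
  if (is.null(segs)) stop("segment-attributes JSON lacks SegmentAttributes", call. = FALSE)
  # dcmqi nests each segment entry inside a one-element array
  flat <- list()
  for (entry in segs) {
    if (is.null(names(entry)) && length(entry) >= 1L && is.list(entry[[1]])) {
      flat <- c(flat, entry)
    } else {
      flat <- c(flat, list(entry))
    }
  }
  lapply(flat, function(s) {
    unknown <- setdiff(names(s), .SEGATTR_KNOWN_SEG)
    if (length(unknown)) {
      warning("ignoring unknown segment key(s): ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    rgb <- s$recommendedDisplayRGBValue
    segment_descriptor(
      label_id = s$labelID,
      segment_label = if (is.null(s$SegmentLabel)) paste0("segment ", s$labelID) else s$SegmentLabel,
      category_code = .code_from_json(s$SegmentedPropertyCategoryCodeSequence,
                                      c("M-01000", "SRT", "Morphologically Altered Structure")),
      type_code = .code_from_json(s$SegmentedPropertyTypeCodeSequence,
                                  c("M-35000", "SRT", "Hemorrhage")),
      display_color_rgb = if (is.null(rgb)) c(216L, 38L, 38L) else unlist(rgb),
      algorithm_type = if (is.null(s$SegmentAlgorithmType)) "AUTOMATIC" else s$SegmentAlgorithmType,
      algorithm_name = if (is.null(s$SegmentAlgorithmName)) "ctqv" else s$SegmentAlgorithmName
    )
  })
}

#' Write segment descriptors as dcmqi-style JSON
#' @param descriptors List of [segment_descriptor()].
#' @param path Output path.
#' @param body_part,content_creator,series_description Document-level fields.
#' @return `path`, invisibly.
#' @export
write_segment_attributes <- function(descriptors, path,
                                     body_part = "ABDOMEN",
                                     content_creator = "ctqv",
                                     series_description = "Segmentation") {
  descriptors <- .check_descriptors(descriptors)
  doc <- list(
    BodyPartExamined = body_part,
    ContentCreatorName = content_creator,
    SeriesDescription = series_description,
    SegmentAttributes = lapply(descriptors, function(d) list(list(
      labelID = d$label_id,
      SegmentLabel = d$segment_label,
      SegmentAlgorithmType = d$algorithm_type,
      SegmentAlgorithmName = d$algorithm_name,
      SegmentedPropertyCategoryCodeSequence = list(
        CodeValue = d$category_code[1],
        CodingSchemeDesignator = d$category_code[2],
        CodeMeaning = d$category_code[3]),
      SegmentedPropertyTypeCodeSequence = list(
        CodeValue = d$type_code[1],
        CodingSchemeDesignator = d$type_code[2],
        CodeMeaning = d$type_code[3]),
      recommendedDisplayRGBValue = d$display_color_rgb
    )))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
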