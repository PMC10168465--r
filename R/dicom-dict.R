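# Data dictionary for the subset of the DICOM standard this pipeline touches:
# CT Image, Segmentation and Comprehensive SR storage IODs plus the identity
# tags of the de-identification profile. Tags are 8-char uppercase hex
# "GGGGEEEE"; VRs follow PS3.6.

.dcm_dict_raw <- c(
  # tag        vr  keyword
  "00020001", "OB", "FileMetaInformationVersion",
  "00020002", "UI", "MediaStorageSOPClassUID",
  "00020003", "UI", "MediaStorageSOPInstanceUID",
  "00020010", "UI", "TransferSyntaxUID",
  "00020012", "UI", "ImplementationClassUID",
  "00020013", "SH", "ImplementationVersionName",
  "00080005", "CS", "SpecificCharacterSet",
  "00080008", "CS", "ImageType",
  "00080016", "UI", "SOPClassUID",
  "00080018", "UI", "SOPInstanceUID",
  "00080020", "DA", "StudyDate",
  "00080021", "DA", "SeriesDate",
  "00080023", "DA", "ContentDate",
  "00080030", "TM", "StudyTime",
  "00080031", "TM", "SeriesTime",
  "00080033", "TM", "ContentTime",
  "00080050", "SH", "AccessionNumber",
  "00080060", "CS", "Modality",
  "00080070", "LO", "Manufacturer",
  "00080080", "LO", "InstitutionName",
  "00080081", "ST", "InstitutionAddress",
  "00080090", "PN", "ReferringPhysicianName",
  "00080100", "SH", "CodeValue",
  "00080102", "SH", "CodingSchemeDesignator",
  "00080104", "LO", "CodeMeaning",
  "0008103E", "LO", "SeriesDescription",
  "00081030", "LO", "StudyDescription",
  "00081040", "LO", "InstitutionalDepartmentName",
  "00081070", "PN", "OperatorsName",
  "00081090", "LO", "ManufacturerModelName",
  "00081115", "SQ", "ReferencedSeriesSequence",
  "00081150", "UI", "ReferencedSOPClassUID",
  "00081155", "UI", "ReferencedSOPInstanceUID",
  "00081199", "SQ", "ReferencedSOPSequence",
  "0008114A", "SQ", "ReferencedInstanceSequence",
  "00082112", "SQ", "SourceImageSequence",
  "00089124", "SQ", "DerivationImageSequence",
  "00100010", "PN", "PatientName",
  "00100020", "LO", "PatientID",
  "00100030", "DA", "PatientBirthDate",
  "00100040", "CS", "PatientSex",
  "00101000", "LO", "OtherPatientIDs",
  "00101040", "LO", "PatientAddress",
  "00102154", "SH", "PatientTelephoneNumbers",
  "00120062", "CS", "PatientIdentityRemoved",
  "00120063", "LO", "DeidentificationMethod",
  "00180050", "DS", "SliceThickness",
  "00180088", "DS", "SpacingBetweenSlices",
  "00181030", "LO", "ProtocolName",
  "0020000D", "UI", "StudyInstanceUID",
  "0020000E", "UI", "SeriesInstanceUID",
  "00200010", "SH", "StudyID",
  "00200011", "IS", "SeriesNumber",
  "00200013", "IS", "InstanceNumber",
  "00200032", "DS", "ImagePositionPatient",
  "00200037", "DS", "ImageOrientationPatient",
  "00200052", "UI", "FrameOfReferenceUID",
  "00201041", "DS", "SliceLocation",
  "00209111", "SQ", "FrameContentSequence",
  "00209113", "SQ", "PlanePositionSequence",
  "00209116", "SQ", "PlaneOrientationSequence",
  "00209157", "UL", "DimensionIndexValues",
  "00280002", "US", "SamplesPerPixel",
  "00280004", "CS", "PhotometricInterpretation",
  "00280008", "IS", "NumberOfFrames",
  "00280010", "US", "Rows",
  "00280011", "US", "Columns",
  "00280030", "DS", "PixelSpacing",
  "00280100", "US", "BitsAllocated",
  "00280101", "US", "BitsStored",
  "00280102", "US", "HighBit",
  "00280103", "US", "PixelRepresentation",
  "00281052", "DS", "RescaleIntercept",
  "00281053", "DS", "RescaleSlope",
  "00289110", "SQ", "PixelMeasuresSequence",
  "0040A010", "CS", "RelationshipType",
  "0040A040", "CS", "ValueType",
  "0040A043", "SQ", "ConceptNameCodeSequence",
  "0040A050", "CS", "ContinuityOfContent",
  "0040A160", "UT", "TextValue",
  "0040A168", "SQ", "ConceptCodeSequence",
  "0040A300", "SQ", "MeasuredValueSequence",
  "0040A30A", "DS", "NumericValue",
  "004008EA", "SQ", "MeasurementUnitsCodeSequence",
  "0040A375", "SQ", "CurrentRequestedProcedureEvidenceSequence",
  "0040A491", "CS", "CompletionFlag",
  "0040A493", "CS", "VerificationFlag",
  "0040A730", "SQ", "ContentSequence",
  "00620001", "CS", "SegmentationType",
  "00620002", "SQ", "SegmentSequence",
  "00620003", "SQ", "SegmentedPropertyCategoryCodeSequence",
  "00620004", "US", "SegmentNumber",
  "00620005", "LO", "SegmentLabel",
  "00620008", "CS", "SegmentAlgorithmType",
  "00620009", "LO", "SegmentAlgorithmName",
  "0062000A", "SQ", "SegmentIdentificationSequence",
  "0062000B", "US", "ReferencedSegmentNumber",
  "0062000D", "US", "RecommendedDisplayCIELabValue",
  "0062000F", "SQ", "SegmentedPropertyTypeCodeSequence",
  "00700080", "CS", "ContentLabel",
  "00700081", "LO", "ContentDescription",
  "00700084", "PN", "ContentCreatorName",
  "52009229", "SQ", "SharedFunctionalGroupsSequence",
  "52009230", "SQ", "PerFrameFunctionalGroupsSequence",
  "7FE00010", "OW", "PixelData"
)

.dcm_dict <- local({
  m <- matrix(.dcm_dict_raw, ncol = 3, byrow = TRUE)
  data.frame(tag = m[, 1], vr = m[, 2], keyword = m[, 3], stringsAsFactors = FALSE)
})

.dcm_tag_by_keyword <- stats::setNames(.dcm_dict$tag, .dcm_dict$keyword)
.dcm_vr_by_tag <- stats::setNames(.dcm_dict$vr, .dcm_dict$tag)
.dcm_keyword_by_tag <- stats::setNames(.dcm_dict$keyword, .dcm_dict$tag)

#' Look up the tag for a DICOM attribute keyword
#' @param keyword DICOM keyword, e.g. `"PatientName"`, or an 8-char hex tag.
#' @return 8-character uppercase hex tag string `"GGGGEEEE"`.
#' @keywords internal
dcm_tag <- function(keyword) {
  if (grepl("^[0-9A-Fa-f]{8}$", keyword)) return(toupper(keyword))
  tag <- .dcm_tag_by_keyword[[keyword]]
  if (is.null(tag)) stop("unknown DICOM keyword: ", keyword, call. = FALSE)
  tag
}

dcm_vr_of <- function(tag) {
  vr <- .dcm_vr_by_tag[[tag]]
  if (is.null(vr)) "UN" else vr
}

# Well-known UIDs
DCM_UID <- list(
  explicit_vr_le     = "1.2.840.10008.1.2.1",
  implicit_vr_le     = "1.2.840.10008.1.2",
  ct_image_storage   = "1.2.840.10008.5.1.4.1.1.2",
  segmentation_storage = "1.2.840.10008.5.1.4.1.1.66.4",
  comprehensive_sr   = "1.2.840.10008.5.1.4.1.1.88.33",
  verification       = "1.2.840.10008.1.1"
)
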