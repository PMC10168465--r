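Package: ctqv
Title: Shadow-Testing Pipeline for CT Segmentation Models with DICOM SEG/SR Output
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A vendor-agnostic store-and-forward pipeline for shadow testing of
    CT segmentation models alongside a clinical PACS workflow. Provides a
    DICOM router with series filtering, de-identification with consistent UID
    remapping, and timeout-based series-completion detection; geometry-faithful
    DICOM to NIfTI conversion; a pluggable NIfTI-in/NIfTI-out segmentation
    backend contract with a deterministic Hounsfield-threshold reference
    backend; DICOM Segmentation (SEG) object encoding and decoding; voxel-count
    volumetry in millilitres; and DICOM Structured Report (SR) measurement
    documents. A synthetic CT phantom generator with analytically known lesion
    volumes provides the test substrate, so the full pipeline is exercised
    without clinical data or trained model weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate:
    'ctqv-package.R'
    'dicom-dict.R'
    'dicom-io.R'
    'uid.R'
    'core-model.R'
    'record.R'
    'convert.R'
    'seg-codec.R'
    'quantify.R'
    'backend.R'
    'segment-attributes.R'
    'router.R'
    'phantom.R'
    'config.R'
    'pipeline.R'
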