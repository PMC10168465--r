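# Example site configuration for the ctqv pipeline.
# AE titles must be pairwise distinct; unknown keys are rejected.
router:
  ae_title: CTQV_ROUTER
  host: 127.0.0.1
  port: 11112
archive:
  ae_title: ARCHIVE
  host: 127.0.0.1
  port: 11113
processor:
  ae_title: DLHOST
  host: 127.0.0.1
  port: 11114
series_filter:
  mode: substring          # substring | regex | exact
  patterns: ["PV", "PORTAL"]
  match_field: series_description
  case_sensitive: false
timeout_seconds: 30        # quiet period after the last received instance
backend:
  kind: threshold_stub     # threshold_stub | external_command
  hu_low: 40
  hu_high: 80
  min_component_voxels: 0
  keep_largest_only: false
  # For a real model (nnU-net or any NIfTI-in/NIfTI-out tool):
  # kind: external_command
  # command: "segment_model --in {input_nifti} --out {output_nifti}"
  # timeout_seconds: 1800
segment_attributes_path: segment_attributes.json
log_level: info
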