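---
title: "ctqv: pipeline design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctqv: pipeline design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Segmentation models for cross-sectional imaging are trained and evaluated
on NIfTI volumes, but clinical images live in PACS as per-slice DICOM
objects, and clinicians can only see results that come back as DICOM. A
shadow-testing deployment therefore needs four pieces of plumbing between
the PACS and the model: (i) a store-and-forward router that receives the
pushed study, keeps only the series of interest and de-identifies it;
(ii) geometry-faithful DICOM-to-NIfTI conversion; (iii) encoding of the
model's label mask as a DICOM Segmentation (SEG) object co-registered to
the source series; and (iv) a volume measurement, taken from the SEG pixel
data itself, delivered as a DICOM Structured Report (SR). `ctqv`
implements exactly this loop and a synthetic phantom substrate to verify
it end to end, with no clinical data and no trained weights.

## Series completion by receive timeout

DICOM gives a storage receiver no reliable end-of-series signal: instances
arrive as independent C-STOREs, and instance-count tags are often absent
or wrong mid-transfer. The router therefore declares a series complete
when a *quiet period* elapses: no new instance for `timeout_seconds`
(default 30 s, site-adjustable). Two consequences are deliberate:

* **Safety, not liveness, is guaranteed.** A series is never converted
  before its quiet period reaches the timeout (this is the property the
  test suite checks against a brute-force replay oracle over randomized
  multi-series event traces). Conversely, a transfer that stalls longer
  than the timeout *will* split a series in two; the second fragment forms
  a new buffer. The timeout must be chosen above the PACS's worst
  inter-instance gap.
* **Timestamps are injected.** Every router operation takes `now` from the
  caller, and the loopback deployment drives a simulated clock. Completion
  therefore cannot be affected by wall-clock jumps, and the full service
  loop is testable in milliseconds of real time while modelling the 30 s
  deployment timeout faithfully.

A completed series is dispatched to both peers serially (one series at a
time, matching a single dispatch queue); peer failure is retried 3 times
with fixed spacing, after which the series stays `complete` on the router
and parked in the spool for operator-free retry. Filtered-out series are
acknowledged with DIMSE success and discarded: refusing the C-STORE would
surface errors on the sending PACS, which a shadow deployment must never
do.

The router's transport is a function-call peer interface (`dir_peer()`
persists objects as Part-10 files); the DIMSE wire protocol itself is out
of scope, as the archive and viewer are external systems in the targeted
deployment. `serve_loopback()` wires router, processing host and stub
archive in-process, which is the configuration every end-to-end test and
the acceptance script exercise. An earlier design question — whether the
router should issue C-MOVE retrievals — was resolved in favour of pure
C-STORE push: the store-and-forward flow never needs a retrieve service.

## De-identification

The default profile is a documented subset of the DICOM Basic
Confidentiality Profile: remove patient name/ID/birth date/address/phone,
other-patient IDs, institution, department and operator names, referring
physician and accession number; set `PatientIdentityRemoved = YES`; strip
all private tags (overridable); coarsen dates to year precision; and remap
every Study/Series/SOP/FrameOfReference UID. Choices worth stating:

* Removal and replacement apply at **every nesting level** (sequences
  included), and the audit test re-scans every object at the archive for
  any tag of the remove list.
* **UID remapping uses fresh random UIDs** from the session RNG under the
  `2.25` arc, recorded in a session `uid_map` so the study/series/instance
  tree stays linked. Hashing originals was rejected because a keyed
  dictionary attack on hashed UIDs would re-link patients; a cryptographic
  RNG would be marginally preferable to R's session RNG, but reproducible
  test runs require seedability, and the linkage map never leaves the
  session either way.
* **Dates become `YYYY0101`** rather than being removed: ordering across
  years survives, day-level identity does not, and the value remains a
  valid DA on write.
* **Geometry tags are constitutionally protected**: a profile listing
  position, orientation, spacing, rescale or pixel-data tags is rejected
  at construction, because volumetry is meaningless on altered geometry.
* Burned-in pixel annotations are *not* detected or removed; this is a
  documented non-goal.

## Geometry conventions

Internal patient coordinates are LPS (the DICOM convention), millimetres.
`volume_geometry` stores the origin as the *center* of voxel (0,0,0) —
DICOM's Image Position (Patient) — plus row/column direction cosines and
the (row, column, slice) spacings. Slices are ordered by the scalar
projection of position onto the slice normal (row × column direction),
with ties broken by instance number then SOP UID. The inter-slice spacing
is the **median of consecutive position increments**, with every increment
required to lie within 10% of that median (a named geometry error
otherwise, pointing at the offending gap); the Spacing Between Slices tag
is ignored whenever positions exist, because positions are authoritative
and the tag is frequently wrong in the wild. A single-slice series falls
back to Slice Thickness. NIfTI affines are RAS: the LPS coordinates with
the first two axes negated — one fixed sign rule, asserted by round-trip
tests to 1e-4 mm on randomized oblique geometries. Gantry-tilted or
otherwise non-orthogonal acquisitions are rejected.

## SEG encoding

Binary segmentations only (one bit per voxel); fractional SEGs are
rejected on decode as an unsupported variant, since the pipeline's masks
are hard labels. Per segment, only slices containing at least one voxel
are emitted as frames (frame economy), each frame carrying its plane
position, segment number and a derivation reference to the source slice's
SOP instance; plane positions make reconstruction unambiguous. Bits are
packed LSB-first and contiguously across frames, as the standard requires.
The SEG keeps the (anonymized) study and frame-of-reference UIDs and gets
a fresh series UID; it references the source series instance by instance.
Decoding places frames at their plane positions — onto the caller's grid
when supplied, else onto a minimal inferred grid — and resolves
overlapping segments to the **highest segment number**, with a warning
(documented, tested). Display colors convert RGB → CIELab under the sRGB
transfer function and D65 illuminant, scaled to the 16-bit encoding the
standard uses. An all-background mask produces **no SEG at all** (an
`empty_segmentation` marker): a frameless SEG is non-conformant, and an
explicit "no finding" SR is out of scope, so the router forwards nothing.

The SEG references the *anonymized* UID tree: de-identification happens at
ingest, before either peer sees the series, so the original UIDs are not
available downstream by construction.

## Volumetry and the SR

Volume is binary voxel counting: count × (product of spacings) / 1000,
reported to 0.1 mL, rounding half away from zero (the reporting rule is a
stated choice; ties at 0.05 mL go up). No partial-volume weighting — a
voxel is in or out, which keeps the SEG-side and NIfTI-side measurements
comparable voxel for voxel; the acceptance suite requires them to agree
*exactly* at 0.1 mL across randomized phantoms. The SR is a minimal
measurement report (a container per segment holding a coded "Volume"
numeric item in UCUM millilitres, a tracking label and a human-readable
summary line), not full TID 1500 conformance, which a single volume
statement does not need. The SR shares the study UID with the images and
references both the SEG instance and the source series as evidence.

## Segmentation backends

The backend contract is deliberately thin: an image volume in, a label
volume on the identical grid out. The deterministic threshold stub (label
1 where `hu_low ≤ HU ≤ hu_high`) exists so that every pipeline property
can be tested with an exactly predictable mask; its optional component
filtering uses **26-connectivity** (face/edge/corner), the common
convention in medical image analysis, implemented as graph components over
a vectorised neighbour edge list and verified against a breadth-first
search oracle. `keep_largest_only` breaks size ties toward the component
with the lowest linear voxel index. The external adapter runs any command
with `{input_nifti}`/`{output_nifti}` placeholders under a wall-clock
timeout and validates the returned mask (shape, affine to 1e-3 mm,
non-negative integer labels, values within 1e-6 of an integer rounded) —
this is the nnU-net integration point, and it is tested with synthetic
commands, never with model weights.

## The phantom generator

`phantom_spec()` emulates the *series shape* of the pipeline's target
input — portal-venous abdominopelvic CT archived at 3 mm section
thickness, 512×512 axial matrices, 91–203 slices per study
(`study_scale_spec()` draws from exactly these ranges, with one or two
ellipsoid lesions whose analytic volumes fall in 28.0–924.7 mL) — and
nothing else. Voxel membership is by center inclusion with no
anti-aliasing, and the image intensities are generated by the *same* rule
as the truth mask, so a noise-free phantom thresholds back to its truth
voxel for voxel; that is what makes "SR volume equals oracle volume to
0.1 mL" a meaningful exact test rather than a tolerance test. Stored
pixels are 16-bit with rescale slope 1 / intercept −1024, exercising the
rescale path. Gaussian HU noise is available (seeded, reproducible) and is
used only in robustness tests; tests asserting exact equality run at noise
0 by design. Pixel spacing defaults to 400 mm / 512 ≈ 0.78 mm, a typical
abdominal field of view.

What the phantom deliberately does **not** model: anatomy and texture,
partial-volume blur at lesion boundaries, contrast-phase or scanner
effects, lesions that approach the image intensity distribution of real
hematomas. Passing tests therefore demonstrate that the *plumbing* —
routing, de-identification, geometry, encoding, measurement — is exact;
they say nothing about segmentation accuracy on clinical data, which is a
property of the model behind the backend contract, not of this package.
Voxelization error against the analytic ellipsoid volume decreases with
spacing and is below 5% at 1 mm for lesions ≥ 4 mL (below 3% for the
pipeline-recovered volume in the acceptance checks).

## Numerical and degenerate-input choices

* Orthonormality of direction cosines: 1e-4; mask co-registration: 1e-3 mm;
  geometry round-trip assertion: 1e-4 mm.
* DS values are written with up to 10 significant digits (within the
  16-byte VR limit), more than the 1e-4 mm geometry tolerance needs.
* Duplicate C-STORE of the same SOP instance overwrites the buffered copy
  (idempotent re-send); an undecodable dataset gets a DIMSE error status
  and is never buffered; an empty-but-complete buffer is a precondition
  violation.
* One series failing inside `run_local()` records an error row and does
  not abort the other series.
* Configs are strictly validated: unknown keys (at any level), duplicate
  AE titles, non-compiling regexes and non-positive timeouts are named
  errors — a typo must not silently disable a site setting.

## Problem sizes in the test suite

The suite runs at sizes chosen to keep the full check fast while covering
the deployment scale once: randomized phantoms for the volumetry
equivalence property use 20–40 voxel grids (50 cases); SEG round-trips use
up to 16³ grids (200 cases); geometry round-trips use 100 randomized
oblique geometries; completion safety replays 1000 randomized event
traces on the simulated clock; and one full-scale phantom (512×512,
91–203 slices at 3 mm) flows through the complete loopback deployment.
`scripts/acceptance.R` recomputes all of these from scratch under a
caller-supplied seed.

## Known limitations

* No DIMSE wire protocol (TLS, association negotiation); the peer
  interface is in-process/file-based by design.
* Binary SEG only; no RT-STRUCT, no enhanced multi-frame CT input.
* De-identification is a documented profile subset, not a certified
  de-identifier; burned-in annotations are untouched.
* Volumetry is voxel counting: no sub-voxel surface estimation, and no
  longitudinal comparison.
* The timeout completion rule trades a fixed latency floor for
  protocol-independence and can split a stalled transfer (see above).
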