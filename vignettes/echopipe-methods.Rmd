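---
title: "echopipe: models, quality gates and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{echopipe: models, quality gates and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echopipe)
```

## The problem and the pipeline

Quantitative echocardiographic measurements — left ventricular ejection
fraction (LVEF) and left atrial volume index (LAVI) in this package — are
rarely available retrospectively at database scale, because each one
requires picking the right recordings out of a heterogeneous exam,
finding the right frames, and tracing chamber borders. `echopipe`
structures that task as three phases:

1. **Curation** — classify each recording's modality and B-mode view,
   gate on classifier confidence, and select the clips each measurement
   needs;
2. **Measurement extraction** — resolve end-diastole (ED) and end-systole
   (ES) frames, quality-control the segmentations, and compute biplane
   volumes;
3. **Analysis** — Bland–Altman agreement against a reference, subgroup
   stratification, and a feasibility funnel accounting for every
   excluded exam.

The learned components that a production deployment would use (modality
and view classifiers, an event-detection network, two independent
segmentation networks) are *not* part of the package. Each sits behind a
small backend contract (`classifier_backend()`, `timing_backend()`), and
the package ships an `oracle` backend that reads the synthetic ground
truth, a `noisy` backend with seeded label flips, and a `none`/`offset`
timing backend for failure injection. All pipeline logic — gating,
selection, fallback, reconciliation, exclusion accounting — is exercised
end to end with these.

## Curation rules

- **Modality taxonomy** (8 classes): 2D/3D B-mode, colour flow, M-mode,
  PW/CW Doppler, contrast, tissue Doppler. Only 2D B-mode proceeds to
  view classification; transoesophageal-only exams are excluded.
- **View taxonomy** (13 labels) covers parasternal, apical, subcostal,
  TEE and unknown, including the LV-focused A4C/A2C zoom variants.
- **Confidence gate**: a clip is eligible only with view-classification
  confidence ≥ 0.85 (inclusive). The gate threshold is configurable
  (`pipeline_config(confidence_threshold =)`).
- **Hierarchical selection for LVEF**: per chamber-slot (A4C, A2C)
  independently, LV-focused variants are preferred (less foreshortening
  risk), standard views are the fallback. For LAVI only standard views
  are used, since the LV-focused zoom crops the atrium. When several
  gated-in clips fill one slot, all are kept and their measurements
  averaged.
- **Gate-then-prefer**: confidence gating is applied *before* the
  focused/standard preference, so a low-confidence focused view loses to
  a high-confidence standard view. The opposite order (prefer first,
  then gate) would discard exams whose focused clip happens to be
  uncertain even when a perfectly good standard clip exists; we consider
  that clearly unintended, but the choice was genuinely open and is
  centralized in `select_slots()`.
- **Exclusion precedence** when several things are wrong at once:
  no B-mode > missing A4C > missing A2C > low view confidence. Every
  excluded exam carries exactly one primary machine-readable reason, so
  funnel counts partition the cohort.

Regional image-quality scores in [0, 5] (as produced by regional
quality-assessment networks for apical views) are averaged and rounded to
an integer exam-level class. Rounding is **half-up** — deterministic and
the convention radiographers expect — rather than R's default
round-half-even; the same rule converts regression milliseconds to
frames.

## Timing

ED and ES are, physiologically, mitral and aortic valve closure. The
event-detection backend proposes frame indices; independently, the ECG
heart rate predicts the ED→ES interval via the sex-specific linear
regressions

```
ES = ED + 498 − 1.60 · HR   (male,   ms)
ES = ED + 522 − 1.77 · HR   (female, ms)
```

converted to frames with half-up rounding at the clip's frame rate. The
two sources are reconciled per cycle: the network result is kept unless
it deviates from the regression by more than 5 frames (deviation = max
over the ED and ES differences; exactly 5 is kept), in which case — or
when the network returns nothing — the regression result is used. Both
sources absent is a `timing_unavailable` exclusion, never a silent
default.

Two points the data model makes explicit rather than guessing:

- The regression only predicts ES *given* ED. The ED anchor must come
  from the manifest's cycle annotation (synthetic data) or an R-wave
  reference when ingesting real files; a recording without an anchor or
  heart rate is excluded from the fallback path with a reason code.
- Whether the 5-frame cutoff applies per event or jointly is an open
  choice; we use the maximum over both events (the conservative
  reading), configurable via `timing_cutoff_frames`.

## Geometry

`extract_long_axis()` finds the chamber axis from second-order moments,
intersects it with the mask, and labels the wider end (perpendicular
extent averaged over the 10 % of the axis nearest each endpoint) as the
base. `disc_diameters()` divides the axis into 20 equal slabs and
measures the full perpendicular extent (max-chord, i.e. caliper
semantics) per one-pixel layer, linearly interpolated at each slab
center. Interpolating at the center matters: taking the widest chord
anywhere inside a slab-wide band inflates volumes by ≈ 2 % at 0.5 mm/px,
because a slab's widest chord always sits on its ventricle-center side.
`biplane_simpson()` then applies

```
V = (π/4) · (L/n) · Σ aᵢ·bᵢ
```

with `L` the longer of the two view lengths (if the two views disagree by
more than 20 % the result carries a foreshortening warning flag, but is
not rejected). Volumes are in mL; nothing is rounded internally.

Numerical conventions: masks are logical matrices, row-major, origin
top-left; pixel (r, c) has its center at (r, c); lengths measured from
pixel extents add one pixel to center-to-center spans. Degenerate masks
(fewer than 50 px, or disconnected — checked with `EBImage::bwlabel`)
yield an `invalid_segmentation` exclusion signal, not an error.

The **dual-segmentation Dice gate** compares the primary and secondary
mask at the ED and ES frames actually measured; Dice ≥ 0.8 (inclusive)
passes. A failing frame drops that clip; the exam is excluded only when
no clip survives. Two empty masks are defined to agree (Dice 1).

BSA uses Mosteller `√(W·H)/60` by default (the echo-lab convention);
DuBois is available via `pipeline_config(bsa_formula = "dubois")`.

## The synthetic phantom

`generate_exam()` models the LV as a *full prolate spheroid* with
semi-axes `a ≥ b = c`. That choice is deliberate: the biplane Simpson
limit for an ellipsoid is the closed form `π/6·L·D₁·D₂`, so the geometry
core has an exact analytic oracle. Real ventricles are truncated at the
mitral plane and asymmetric; a truncated/realistic shape family is a
documented extension, not the default, and consequently the phantom does
not test base-plane detection the way clinical masks would — that
heuristic is the main real-data risk.

Details:

- ED semi-axes follow from the requested EDV and an aspect ratio
  (default `a/b = 1.8`); ES keeps 90 % of the long axis (longitudinal
  shortening) with `b` solved from the ESV. Semi-axes interpolate with a
  cosine ease between ED and ES, so masks exist at any frame.
- A4C and A2C are the two orthogonal long-axis planes; for a spheroid
  their cross-sections are identical ellipses, which also gives the
  orthogonal-plane consistency invariant (equal long-axis lengths) for
  free. The LA is an analogous spheroid realized at ES.
- ES frames are placed by the same sex-specific regression the timing
  module uses, so the network and ECG sources agree by construction
  unless a corruption disables or offsets the network.
- Masks are rasterized at the frames the measurement will request
  (ED/ES and their corrupted-timing counterparts); `mask_frames = "all"`
  rasterizes every frame for convergence studies. Dense all-frame stacks
  for 100-exam cohorts would spend gigabytes on frames nothing reads.
- The secondary ("second network") mask equals the primary unless
  `dice_degradation > 0`, in which case an angular sector of the
  boundary — sector width that fraction of the full boundary — is pulled
  inward to 70 % of its radius. This is an analytic stand-in for a
  segmenter that loses part of the border; the achieved Dice is recorded
  in the ground truth (degradation 1 lands near Dice 0.66, safely below
  the 0.8 gate). We chose this over morphological erosion of random arcs
  because it is exactly reproducible and needs no structuring-element
  bookkeeping, at identical test value.
- All randomness flows from one integer seed (cohort seeds spawn
  per-exam seeds); generation restores the caller's RNG state.

**What passing tests do and do not show.** The phantom validates the
pipeline's logic (gates, fallbacks, accounting) and the geometry's
numerics (discretization error, convergence, invariances). It does not
emulate speckle, myocardial texture, probe geometry, foreshortened
apexes, arrhythmic cycles, or classifier errors on real images — so test
results bound implementation error, not clinical accuracy.

## Cohort study conditions

`generate_cohort()` draws uniformly from ranges chosen to span a mixed
clinical population: EDV 80–200 mL, EF 20–70 %, LA ESV 30–90 mL, heart
rate 55–95 bpm, height 150–195 cm, weight 50–110 kg, equal sexes,
frame rate 50 Hz, pixel spacing 0.5 mm/px. The test suite and the
worked examples use cohorts of 8–100 exams — large enough for funnel and
recovery statistics while keeping a full run in tens of seconds.
Corruption mixes take exact counts (assigned randomly without overlap)
or independent Bernoulli probabilities per exam.

At these conditions the measured recovery, computed by the tests
themselves, is: single-phantom EF within 2 % absolute of truth;
cohort-mean signed EF error within ±1 % absolute and LAVI within
±2 mL/m²; mean biplane volume error ≤ 2 % relative at 0.5 mm/px with
error decreasing as spacing is halved (averaged over geometries — a
single phantom near the discretization noise floor can fluctuate
non-monotonically between adjacent resolutions).

## Data model and formats

Manifests are versioned JSON (`schema_version`), with masks either as
8-bit binary PNGs referenced by relative path (human-inspectable,
diff-able) or inline row-major run-length encodings. Frame indices are
0-based on disk and 1-based in the R API. Each recording can carry up to
four mask stacks (`lv`/`la` × `primary`/`secondary`), because the LV and
LA paths consume different structures segmented from the same standard
clips. Pixel spacing is isotropic; anisotropic data is rejected at
construction. A minimal DICOM Part-10 reader (explicit VR little-endian,
public tags only) seeds recordings with study UID, frame count, frame
rate and heart rate; vendor-private tags and pixel data are out of
scope.

## Known limitations

- The prolate-spheroid phantom cannot probe base-plane detection or
  foreshortening on realistic shapes (see above).
- The principal-axis/max-chord construction assumes roughly convex,
  single-component masks; heavily lobed segmentations would need the
  invalid-segmentation path.
- `timing_source` is reported per exam as `network`, `ecg_regression`,
  or `mixed` when averaged clips resolved differently.
- The DICOM reader handles explicit-VR little-endian files without
  undefined-length sequences; anything else errors with a clear message
  rather than guessing.
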