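Package: echopipe
Title: Automated Curation and Biplane Volume Measurement for Echocardiography Exams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for organizing transthoracic echocardiography exams,
    gating recordings through quality-control rules (view-classification
    confidence, dual-segmentation Dice agreement, timing reconciliation
    against ECG-based regression), computing biplane Simpson left
    ventricular volumes, ejection fraction, left atrial volume and left
    atrial volume index from binary segmentation masks, and summarizing
    agreement with reference measurements via Bland-Altman statistics and
    a stage-by-stage feasibility funnel. Learned components (modality,
    view, timing and segmentation networks) sit behind pluggable backend
    interfaces; a synthetic ellipsoid phantom generator with analytic
    ground truth makes every pipeline stage testable without clinical
    data or trained models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    png,
    EBImage,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
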