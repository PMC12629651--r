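# echopipe

Automated curation and biplane volume measurement for echocardiography
exams.

Echo labs accumulate far more imaging than ever gets measured: a
transthoracic exam holds dozens of recordings across modalities and views,
and retrospective manual tracing is slow and operator-dependent. `echopipe`
implements the measurement side of that problem as a reusable pipeline:
it organizes exams (studies → recordings → frames), gates recordings
through explicit quality-control rules, and computes left ventricular
volumes, ejection fraction and the left atrial volume index from binary
segmentation masks — with every learned component (modality classifier,
view classifier, event-detection network, segmentation networks) behind a
pluggable backend interface. A synthetic phantom generator with exact
analytic ground truth makes the whole pipeline testable without clinical
data or trained models.

## What it computes

For each exam that survives curation:

- **Biplane Simpson (method of disks) volumes.** From one apical
  four-chamber (A4C) and one two-chamber (A2C) mask,
  `V = (π/4)·(L/n)·Σ aᵢ·bᵢ`, with `aᵢ`, `bᵢ` the disc diameters from the
  two views and `L` the longer long-axis length (`n = 20` disks).
- **Ejection fraction** `EF = (EDV − ESV)/EDV · 100%`.
- **LA volume index** `LAVI = LAESV / BSA`, with Mosteller
  `BSA = √(weight·height)/60` (weight kg, height cm).
- **Timing.** End-diastole/end-systole frames come from an event-detection
  backend, cross-checked against the ECG heart-rate regressions
  `ES = ED + 498 − 1.6·HR` (male) and `ES = ED + 522 − 1.77·HR` (female,
  ms); a network result deviating by more than 5 frames — or absent —
  falls back to the regression.
- **Quality gates.** View-classification confidence ≥ 0.85;
  dual-segmentation Dice ≥ 0.8 between primary and secondary masks at the
  frames actually measured.
- **Agreement and feasibility.** Bland–Altman bias/SD and ±1.96·SD limits
  of agreement (with subgroup stratification), plus a stage-by-stage
  feasibility funnel that conserves counts.

## Worked example

Simulate a 20-exam cohort in which 2 exams lack A2C views and 3 carry a
deliberately disagreeing secondary segmentation, then run the full
pipeline:

```r
library(echopipe)
cfg <- pipeline_config()   # confidence 0.85, Dice 0.8, 5-frame cutoff, 20 disks
out <- run_pipeline(cfg, list(
  n = 20, seed = 42,
  corruption_mix = list(
    list(corruption = corruption_spec(drop_views = c("A2C", "A2C_LV_focused")), count = 2),
    list(corruption = corruption_spec(dice_degradation = 1), count = 3))))
print(out$funnel)
print(out$agreement$ef)
```

```
feasibility funnel: 20 exams in, 15 measured (75.0%)
              stage entering excluded surviving pct_of_input
      bmode_present       20        0        20          100
      views_present       20        2        18           90
    confidence_gate       18        0        18           90
   timing_available       18        0        18           90
 segmentation_valid       18        0        18           90
            dice_qc       18        3        15           75
n = 15, bias = -0.169 (SD 0.258), LOA [-0.675, 0.337]
```

The funnel shows exactly the injected corruption: the 2 exams without an
A2C view are excluded at the view stage, the 3 with degraded secondary
masks at the Dice gate, and the remaining 15 are measured. The
Bland–Altman line compares measured EF against the phantoms' analytic
ground truth: a −0.17 % bias with 0.26 % SD, i.e. the geometric core
recovers the true EF to a fraction of a percent at 0.5 mm/px
rasterization. LAVI agreement on the same run is 0.05 ± 0.12 mL/m².

Per-exam results are a plain data frame (also written as `results.csv`):

```
   study_uid   ef_pct  true_ef lavi_ml_m2 dice_ed timing_source exclusion_reason
1 study_0001 64.73540 65.20157   25.47541       1       network             none
2 study_0002       NA 26.93551         NA      NA          <NA>         low_dice
6 study_0006       NA 45.71059         NA      NA          <NA>      missing_A2C
```

A thin command-line front end (`exec/echopipe`) exposes the same steps as
`simulate`, `curate`, `measure`, `analyze` and `run` subcommands over
JSON manifests and YAML configs.

## Scope

The package does not train or ship neural networks, decode vendor-private
DICOM tags, process B-mode pixel data, or handle Doppler/M-mode/contrast
recordings beyond labeling them; see the methods vignette
(`vignettes/echopipe-methods.Rmd`) for the model, its assumptions and
known limitations.
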