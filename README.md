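# ccia

Coronary contrast intensity analysis (CCIA) of angiographic image
sequences, for researchers evaluating image-based, wire-free grading of
coronary artery stenosis against the pressure-wire reference standard.

## The index

A contrast bolus of amount *I* passing a vascular site with flow *Q*
satisfies the Stewart–Hamilton indicator-dilution relation

    Q = I / ∫ C(t) dt

where *C(t)* is the contrast time–intensity curve at the site, so the area
under the curve (AUC) is inversely proportional to local flow. CCIA grades
a stenosis as the AUC ratio between the stenotic region and an equal-sized
region placed 10 mm upstream:

    CCIA = AUC_stenotic / AUC_proximal

Low values indicate hemodynamically severe lesions; values above 1 are
legal and occur in real patients. The reference index is fractional flow
reserve, FFR = (P̄d − Pv)/(P̄a − Pv) → P̄d/P̄a with Pv = 0, cycle-averaged
over ten cardiac cycles.

The package covers the full pipeline:

- **I/O** — multi-page TIFF + JSON sidecar stacks (bit-exact 16-bit round
  trip), multi-frame DICOM (read, via a pydicom bridge), CSV ECG and
  pressure traces, JSON ROI specifications, and the packaged 15-patient
  results table.
- **Curve analysis** — ROI signal extraction, trapezoidal AUC, the CCIA
  index, Stewart–Hamilton flow estimation, automatic placement of the
  equal-sized proximal region along the vessel centerline.
- **Motion stabilization** — ECG R-peak detection and sinus-rhythm gating,
  per-frame cardiac phase, sub-pixel template tracking by normalized
  cross-correlation, and inverse translation to a static-vessel stack.
- **Hemodynamics** — cycle-windowed FFR from paired pressure traces.
- **In-silico phantom** — a mass-conserving 1-D advection–dispersion bolus
  simulator over the nine bench stenosis geometries (30/50/70 % diameter
  stenosis × 6/18/30 mm) under pulsatile flow, rendered as noisy projection
  angiograms with matching pressure traces, ECG and ground-truth motion.
- **Statistical validation** — Pearson correlation reports and a scripted
  re-derivation of the published patient-level results.

## Worked example

Simulate a 50 % × 18 mm stenosis acquisition (300 frames, 10 s, 4 mL of
contrast at 16 mL/s) and grade it:

```r
library(ccia)
cfg   <- simConfig(geometry = stenosisGeometry(0.5, xs = 12), noiseSd = 10)
stack <- simulateStack(cfg)
computeCcia(stack, phantomRoi(cfg), baselineFrames = 15,
            window = c(0.5, max(frameTimes(stack))))
#> CciaResult: CCIA = 0.3281 (AUC stenotic 286.92 / AUC proximal 874.557)
#>   integration window [0.5, 9.97] s
computeFfr(simulatePressures(cfg), period = 1)
#> FfrResult: FFR = 0.9204 (mean Pd 100.00 / mean Pa 108.65 mmHg, Pv 0.0, 10 cycles)
```

The moderate lesion passes about a third of the proximal contrast dose per
unit signal (CCIA 0.33) while dropping ~8.7 mmHg of mean pressure
(FFR 0.92). Across the full nine-geometry grid (`runGrid()`), both indices
decrease strictly with stenosis severity at every length, and FFR also
decreases with lesion length.

The published patient-level validation reproduces from the packaged table:

```r
validateReport()
#> Contrast-intensity validation report
#>   per-patient CCIA matches: 15 / 15
#>   CCIA vs FFR: r = 0.5775, p = 0.02417, n = 15 ...
#>   CCIA vs iFR: r = 0.7578, p = 0.006887, n = 11 ...
```

A thin command-line front end over the same functions lives at
`inst/scripts/ccia-cli.R` (subcommands `compute`, `ffr`, `simulate`,
`stabilize`, `grid`, `validate`).

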