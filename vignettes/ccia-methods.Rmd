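---
title: "Contrast-intensity analysis of coronary stenosis: models and methods"
author: "ccia package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrast-intensity analysis of coronary stenosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccia)
```

## The index and its physiological basis

Coronary contrast intensity analysis (CCIA) grades a stenosis from the
angiogram itself. Within a region of interest the contrast agent produces a
time–intensity curve $C(t)$ — the attenuation of the X-ray image relative to
the pre-injection baseline. By the Stewart–Hamilton indicator-dilution
relation, a bolus of amount $I$ passing a site with flow $Q$ satisfies

$$Q = \frac{I}{\int_0^\infty C(t)\,dt},$$

so the area under the curve (AUC) at a site is inversely proportional to the
local flow. CCIA is the ratio

$$\mathrm{CCIA} = \frac{\mathrm{AUC}_{\mathrm{stenotic}}}{\mathrm{AUC}_{\mathrm{proximal}}}$$

between the stenotic region and an equal-sized region placed upstream.
Values near 1 mean the lesion passes contrast freely; low values mean a
hemodynamically severe lesion. Values above 1 are legal (they occur in real
patients) and are never clamped. The reference index is fractional flow
reserve (FFR), $(\bar P_d - P_v)/(\bar P_a - P_v)$, computed from paired
pressure traces cycle-averaged over the last ten complete cardiac cycles;
with the conventional $P_v = 0$ it reduces to $\bar P_d / \bar P_a$.

Note one asymmetry of conventions worth stating explicitly: written as a
flow ratio, an index of stenosis severity would be
$Q_{\mathrm{stenotic}}/Q_{\mathrm{normal}}$, which under Stewart–Hamilton
equals $\mathrm{AUC}_{\mathrm{normal}}/\mathrm{AUC}_{\mathrm{stenotic}}$.
The operational definition used here and throughout the validation data is
the AUC ratio stenotic ÷ proximal, under which low values indicate severe
lesions; the package follows that operational definition.

## Measurement procedure

- **Signal polarity.** Contrast darkens the image, so the ROI signal is
  `max(0, baseline − frame mean)`, with the baseline taken from the
  pre-injection frames only (`baselineFrames`). The ROI statistic is the
  per-pixel mean; because the two regions have equal pixel counts by
  construction, the CCIA ratio is identical whether a mean or a sum is
  used, and the mean keeps curves comparable across ROI sizes.
- **Proximal region placement.** `defineProximalRoi()` translates the
  stenotic mask upstream along the directed centerline so that its
  downstream boundary sits 10 mm of arc length upstream of the lesion's
  upstream boundary; the translation is a single nearest-pixel vector, so
  the pixel count is preserved exactly. Reading "the end of the stenotic
  area" as the upstream boundary keeps the proximal region strictly
  upstream of any lesion influence.
- **Integration window.** The default window runs from the injection start
  to the last frame of the 10 s acquisition, with no return-to-baseline
  truncation: the recording is expected to outlast the bolus.
- **Trapezoid integration** with linear interpolation at the window edges
  is exact for piecewise-linear curves; on a 1 ms grid the
  $t^2 e^{-t}$ test curve integrates to $\Gamma(3) = 2$ within $10^{-4}$.

## Motion stabilization for in vivo acquisitions

Coronary arteries move with the heart, so in vivo stacks are converted to
static-vessel stacks before analysis:

1. **R-peak detection** (`detectRPeaks`): 5–15 Hz zero-phase Butterworth
   bandpass, squared-derivative envelope with 0.15 s smoothing, peak
   picking with a 0.25 s refractory period, refinement to the local voltage
   maximum. The R–R coefficient of variation gates the analysis:
   stabilization refuses to run above CV = 0.10 (inclusive threshold)
   unless forced, because the method assumes a regular cycle.
2. **Cardiac phase** is assigned per frame as the fractional position in
   the enclosing R–R interval and travels with the track as metadata; it is
   used for quality control and reference-frame selection, not to discard
   frames.
3. **Template matching** (`trackTemplate`): normalized cross-correlation
   (NCC) of a user-chosen template (a stable landmark such as the lesion
   segment or catheter tip) over a $(2r+1)^2$ search window, refined to
   sub-pixel precision by separable parabolic interpolation of the NCC
   peak. NCC is used because the global intensity shifts of contrast
   passage leave it invariant. When the integer peak is an exact match
   (NCC $> 1 - 10^{-9}$) the refinement is skipped: the surface curvature
   then carries no sub-pixel information, only texture asymmetry.
4. **Inversion** (`stabilize`): each frame is translated by minus its
   displacement with bilinear interpolation; out-of-view pixels are filled
   with edge values and flagged in a validity mask.

The motion model is a pure per-frame translation — no rotation or
deformation — which matches a rigid phantom and is an acknowledged
approximation for patients.

## The in-silico phantom

The generator reproduces the bench circulation conditions: nine
axisymmetric stenosis geometries (30/50/70 % diameter stenosis × 6/18/30 mm
total lesion length, 3 mm tapers around a constant throat, 3 mm normal
diameter), pulsatile flow with 25 cm/s mean velocity at 60 bpm and a 60 %
output phase ratio, and the standard injection of 4 mL contrast at 16 mL/s
delivered through 500 mm of upstream tubing, imaged as 300 frames over
10 s at 30 frames/s.

- **Transport** is cross-section-averaged 1-D advection–dispersion,
  $\partial_t(AC) + \partial_x(QC) = \partial_x(AD\,\partial_x C)$, solved
  with a conservative upwind finite-volume scheme (Rcpp kernel) and
  automatic CFL sub-stepping; an unstable configuration raises an error
  rather than being clipped. Mass bookkeeping makes
  `massBalance()` exact to round-off. 3-D CFD is deliberately out of
  scope: the 1-D model provides realistic time–density curves *and* exact
  ground truth.
- **The injector tubing** is modeled as a pure transport delay at the mean
  velocity plus Gaussian temporal spreading of the bolus
  (`injectionSpreadSd`, default 0.5 s). The default approximates laminar
  shear stretching: over tubing of length $L$ the front travels at twice
  the mean velocity, giving a full width of roughly $L/(2\bar v) = 1$ s.
  When the smeared bolus completes within the record it is rescaled so
  exactly the injected amount enters the domain.
- **Rendering** projects the lumen onto a straight-vessel image: pixel
  attenuation = gain × concentration × chord length of the circular lumen,
  subtracted from a flat background, plus seeded Gaussian detector noise,
  clipped at zero and quantized to integer counts (so written stacks
  round-trip bit-exactly through 16-bit TIFF).
- **Geometry layout.** The lesion center sits at 0.65 × the 100 mm domain
  rather than the middle: the 30 mm lesions need 40 mm of upstream room for
  the equal-sized proximal region plus its 10 mm offset.
- **Pressures.** The distal bed is a fixed microvascular resistance
  anchored at 100 mmHg distal pressure under nominal flow:
  $P_d(t) = R_d Q(t)$ and $P_a(t) = P_d(t) + \Delta P(Q(t))$, where
  $\Delta P$ is the lesion-specific Poiseuille integral (in excess of a
  same-length normal vessel, since the shared tubing gradient cancels
  between sensors placed just across the lesion) plus a Borda–Carnot
  expansion loss. This formulation keeps $0 < P_d \le P_a$ pointwise for
  every geometry — a reference aortic waveform with a subtracted loss does
  not: under the mandated constant pump flow the severe geometries would
  drive $P_d$ negative. The aortic waveform that results is synthetic
  plumbing, not a physiological pressure shape.
- **In vivo mode** adds a smooth random background texture (static
  anatomy), a cardiac-phase-locked translation of the whole scene, a
  synthetic ECG with R spikes exactly at cycle starts, and the exact
  per-frame displacements as ground truth.

### What the phantom does and does not emulate

The phantom provides ordinal fidelity — CCIA and FFR decrease strictly with
% diameter stenosis at every length, FFR decreases with length at every
severity — and exact internal ground truth (flow, mass, motion). It does
not reproduce the numeric bench values, which are physical measurements on
hardware with unmodeled losses; they are shipped (`invitroReference()`)
for display only and are never asserted. Real angiograms additionally
contain scatter, beam hardening, curved and branching vessels, respiratory
motion and non-rigid deformation, none of which are modeled; passing the
phantom tests therefore demonstrates correctness of the computational
pipeline, not clinical performance.

One model property deserves emphasis: under pulsatile flow the station AUC
declines slowly downstream (about 6 % over 16 mm at the default
settings) because the inlet source enriches slow diastolic fluid and that
correlation decays as the bolus propagates. The effect is grid-converged
and dispersion-independent — it is indicator-dilution physics under
periodic flow, not a solver artifact — and it means a no-lesion phantom
scores slightly below 1 under pulsatile flow even though it scores 1.000
under constant flow. The same effect plausibly contributes to sub-unity
mild-lesion readings on physical rigs.

## Statistical validation

`validateReport()` re-derives the published patient-level results from the
packaged 15-patient table: every printed CCIA value is recomputed from its
printed intensities (all 15 match at two decimals under round-half-to-even,
R's default rounding), and the two Pearson correlations are reproduced —
CCIA vs FFR $r = 0.5775$ ($n = 15$, $p < 0.05$) and CCIA vs iFR
$r = 0.7578$ ($n = 11$, $p < 0.01$), both computed on the printed
(2 dp) CCIA column, which is what matches the published coefficients at
four decimals. P-values use the $t$ transform with $n - 2$ degrees of
freedom; published bounds are checked as bounds. The nine-model bench
correlation between mean CCIA and FFR is computed and displayed but never
asserted: the printed per-model means do not reproduce the published
coefficient (they give roughly 0.64), so that value must rest on
replicate-level pairings that were not published, and the package refuses
to assert what its inputs cannot reproduce. Replicate summaries use the
sample ($n-1$) standard deviation, undefined (NA) for a single replicate.

## Numerical choices and degenerate inputs

- Time stepping: $\Delta t \le 0.45\,\Delta x/u_{\max}$ and
  $\le 0.25\,\Delta x^2/D$, sub-divided to land exactly on frame times.
- Default grid: $\Delta x = 0.5$ mm (12+ cells across the shortest
  lesion); halving it changes station AUCs by well under 1 %.
- Curves must be strictly increasing in time; AUC windows outside the
  curve support, empty masks, non-positive AUCs, flat ECG traces,
  zero-variance correlation inputs and too-short pressure records all
  raise typed errors rather than returning NaN.
- Pixel coordinates are 1-based (row, column) in memory, matching R
  matrix indexing, and 0-based in the JSON ROI interchange format.
- The test suite runs the phantom at a shortened acquisition (5 s, 150
  frames, 100 mm tubing with proportionally reduced bolus spread); the
  acceptance-grade checks use the full 10 s / 300 frame / 500 mm
  conditions.

## Worked example

```{r example, eval = FALSE}
cfg <- simConfig(geometry = stenosisGeometry(0.5, xs = 12), noiseSd = 10)
stack <- simulateStack(cfg)
res <- computeCcia(stack, phantomRoi(cfg), baselineFrames = 15,
                   window = c(0.5, max(frameTimes(stack))))
res
ffr <- computeFfr(simulatePressures(cfg), period = 1)
ffr
```

A moderate 50 % × 18 mm lesion scores a CCIA near 0.33 with an FFR near
0.92 under the default settings; the full nine-model table comes from
`runGrid()` and feeds `validateReport()` for the ordinal trend checks.
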