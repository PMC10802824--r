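---
title: "Automated left-ventricular strain: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated left-ventricular strain: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echostrain)
```

## The measurement model

`echostrain` measures left-ventricular longitudinal strain from apical-view
echocardiographic image sequences together with per-frame endocardial contour
annotations (in practice produced by a segmentation model; in this package
also by the built-in phantom). The pipeline operates strictly downstream of
segmentation:

1. **Cavity-size curve.** Each frame's annotation is closed with the mitral
   base chord and its shoelace area taken as a cavity-size surrogate. The
   clinical workflow this follows derives a volume curve from dedicated 2-D
   measurements; the chord-closed area is monotone in ventricular size, needs
   nothing but the contour, and only its extrema matter for cycle detection.
2. **Cycle detection.** End-diastole (ED) is a prominent local maximum of the
   smoothed cavity curve, end-systole (ES) the minimum strictly between
   consecutive EDs. Only complete ED-to-ED beats are measured.
3. **Tracking.** The ED contour, resampled to 64 equally spaced points, is
   propagated frame-to-frame by pyramidal Lucas–Kanade optical flow evaluated
   at each point (speckle tracking with a local translation model), then
   blended each frame toward that frame's annotation
   (`w * annotation + (1 - w) * tracked`, annulus-to-annulus arc-fraction
   correspondence).
4. **Strain.** With `L(k)` the traced endocardial length at frame `k`,
   strain is `e(k) = 100 (L(k) - L(ED)) / L(ED)`; shortening is negative.
   Because frame-to-frame tracking accumulates drift, the linear ramp in
   frame index that vanishes at ED and equals the residual at the next ED is
   subtracted, pinning both ends of the beat to zero. GLS is the corrected
   value at ES, averaged over the beats of the selected video; total GLS
   averages the A4C, A2C and A3C views.
5. **Regional strain.** The trace is split into six named segments per A4C
   and A2C view (the apical cap is never reported). Boundaries are fixed at
   ED arc fractions and carried through the beat by point correspondence;
   each segment curve is drift-corrected with its own ramp and its systolic
   peak (most negative value in `[ED, ES]`) reported. Per-segment ramps keep
   the additivity identity exact: the ED-length-weighted mean of the six
   segment curves equals the global curve at every frame.
6. **Quality gates.** Sequential checks with short-circuit semantics decide
   which videos produce measurements: view identification (classifier
   confidence), measurement confidence (tracking residual), heart-rate
   plausibility, end-of-cycle trace displacement, and ECG congruence.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `n_points` | 64 | points | canonical contour resolution; GLS is stable above ~64 points and powers of two keep resampling cheap |
| `stabilization_weight` | 0.5 | – | equal trust in tracker and per-frame annotation |
| `flow$pyramid_levels` | 3 | – | tracks displacements up to tens of pixels at 60–80 fps |
| `flow$window_px` | 15 | px | speckle patch size at typical apical resolution (~0.3–0.5 mm/px) |
| `smoothing_window` | `round(fps / 10)` | frames | suppresses trace jitter without displacing extrema of a symmetric pulse (centered window, shrinking at the edges) |
| `prominence_frac` | 0.05 | – | peak prominence as a fraction of the cavity curve's dynamic range; ties break toward the earlier frame |
| `hr_bounds` | [30, 180] | bpm | closed plausibility interval; the workflow names the check but prints no bounds, so these are configuration values |
| `displacement_tau` | 0.05 | – | end-of-beat mean trace mismatch allowed, as a fraction of the ED arc length |
| `residual_cap` | 0.2 | intensity | cap on the mean per-frame median patch dissimilarity (images are in [0, 1]); operationalizes "measurement confidence", which the source workflow does not define numerically |
| `ecg_tolerance` | 0.1 | s | an R peak must fall within this window of ED; the check is advisory (applied only "if available") unless `ecg_strict` |
| `min_view_confidence` | 0.5 | – | minimum view-classifier confidence for a candidate video |
| `gls_threshold` | −16 | % | impaired-GLS cutoff; a value exactly at the threshold is classed not impaired |

Segment boundaries default to equal arc-length sixths with the apex split at
fraction 0.5 between the two apical segments. The partition rule is not
specified by the clinical workflow this package follows, so it is a
configurable default, not an inferred fact.

## The phantom

The synthetic data generator produces a truncated-ellipse endocardium
(default 75 mm long axis, 45 mm cavity width, 0.5 mm/px) contracting with a
smooth `sin^2` activation pulse (systole ≈ 35% of the beat). The deformation
is built edge-by-edge: every polyline edge keeps its ED direction and scales
its length by `1 + GLS * m_j * s(t) / 100`, where `m_j` is the segment's
shortening modifier (0 = akinetic) and `s(t)` the activation. Because all
edges of a segment share one factor, the programmed global and per-segment
strains are reproduced by the generated contours to floating precision — the
ground truth is exact by construction, not fitted. The base midpoint is
anchored, so the apex moves toward the base as in real long-axis motion.

Rendering lays Gaussian speckle particles in a band around the ED contour
(band coordinates: arc fraction, normal offset; the band extends slightly
past the annulus points because tissue does not end at the trace) and
advects them with the analytic motion, then applies multiplicative per-pixel
noise and a noisy background floor, clamps to [0, 1] and quantizes to 8 bits
(so PNG round trips are lossless). An ECG impulse train is emitted at true
ED times with configurable jitter.

What the phantom does *not* emulate: ultrasound physics (point-spread
function, attenuation, shadowing, clutter), out-of-plane motion, probe
motion, valve apparatus, or annotation error — the phantom's annotations are
its own ground truth. Passing the phantom tests therefore demonstrates that
the measurement chain is correct and stable under speckle-like texture and
multiplicative noise; it does not certify performance on clinical images,
whose segmentation quality dominates in practice.

Cohort generation draws per-study GLS from a normal distribution (default
mean −18%, SD 4%, truncated to the valid range), heart rate uniform in
55–95 bpm, frame rate uniform in 60–80 fps (the acquisition envelope of the
validation data the workflow was built for), and gives a chosen fraction of
studies one akinetic segment in a random A4C or A2C view. Large cohorts are
returned as lazy handles and materialized one study at a time during
analysis, so memory stays bounded by a single study.

## Numerical choices

- **Resampling** uses self-consistent equal-chord placement computed by a
  fixed-point reparametrization iteration (tolerance 1e−12 relative). Unlike
  one-pass equal-arc interpolation, this makes resampling exactly idempotent,
  which downstream correspondence logic relies on; endpoints are preserved
  exactly and arc length to well under 0.5% at 64 points.
- **Drift correction** is a linear ramp in frame index. A correction
  proportional to instantaneous |strain| was considered and rejected as
  opaque; the ramp is the unique linear function with the required boundary
  values, idempotent, and preserves segment additivity.
- **Cycle detection** runs on the smoothed curve with topographic prominence
  filtering; boundary frames are eligible as EDs (a video that starts at ED
  should yield its first beat). Ties break toward the earlier frame.
- **Tracking** restarts at every detected ED, so errors cannot accumulate
  across beats; within a beat the accumulated drift is removed by the ramp.
  The Lucas–Kanade normal equations are solved per point with up to 20
  iterations per pyramid level (convergence 0.01 px); points whose gradient
  matrix is near-singular keep their propagated position. Points leaving the
  image are clamped and flagged; a frame with more than 20% flagged points
  aborts the video's tracking.
- **Statistics** use sample (n−1) standard deviations, 1.96·SD limits of
  agreement, t-based bias confidence intervals, and the Mann–Whitney
  mid-rank AUC (exact under ties, no trapezoids). Shapiro–Wilk is delegated
  to `stats::shapiro.test`.

## Known limitations

- The stabilization blend matches tracked points to annotation points by
  arc fraction. Per-frame annotations carry no temporal correspondence, so
  under non-uniform contraction this matching redistributes tangential
  motion toward the annotation's own parametrization: with `w = 0.5` an
  akinetic segment reads roughly midway between zero and the view GLS rather
  than zero. Global strain is unaffected (it depends only on total length),
  and akinetic segments remain clearly separable from normal ones — the
  regional output is a discriminative score, and peak-strain AUC for induced
  akinesia stays above 0.95 in the packaged experiments. Recovering absolute
  regional strain would require correspondence-aware guidance (e.g.
  normal-only blending), which is deliberately left out to keep the blend
  rule transparent.
- Regional strain is defined for A4C and A2C only; A3C contributes to GLS
  but has no segment scheme here.
- `load_study` reads the package's documented array-stack + JSON sidecar
  dialect (and PNG frame stacks). DICOM ingestion is out of scope in this
  environment.
- Atrial-fibrillation-like irregular rhythms are handled simply by averaging
  all detected beats; no beat classification is attempted.

## Problem sizes in the packaged experiments

The test suite and the acceptance script run, among smaller checks: a
zero-noise three-view phantom study (GLS −20%, 70 fps, HR 75, 3 beats); two
50-study cohorts at speckle noise SD 0.1 (one for GLS agreement against
truth, one with 40% akinetic studies for regional AUC); 30 seeded runs of
the displacement gate; and byte-level determinism comparisons of phantom
data, reports and cohort tables. These sizes were chosen so the full suite
exercises every stage end-to-end on a single CPU while remaining exactly
reproducible from the seeds.
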