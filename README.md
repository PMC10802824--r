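# echostrain

Automated measurement of left-ventricular (LV) global and regional
longitudinal strain from apical-view echocardiography, downstream of
endocardial segmentation. Given an image sequence and per-frame endocardial
contour annotations, the package detects cardiac cycles from the cavity-size
curve, tracks the end-diastolic trace through each beat with pyramidal
Lucas–Kanade speckle tracking stabilized by the annotations, and converts
tracked contour lengths into drift-corrected strain curves.

The core quantity is global longitudinal strain,

```
GLS = 100 · (L(ES) − L(ED)) / L(ED)   [%]
```

with `L` the traced endocardial length, evaluated on the drift-corrected
curve (a linear ramp removes the spurious strain accumulated by
frame-to-frame tracking so each beat returns to zero at the next
end-diastole). Per-view GLS averages the beats of the highest-confidence
video of that view; total GLS averages the A4C, A2C and A3C views. Regional
strain applies the same length-change measure to six named segments per A4C
and A2C view (apical cap excluded) and reports the systolic peak per
segment. Sequential quality gates — view identification, measurement
confidence, heart rate, trace displacement, ECG congruence — decide which
videos are measured, with one primary exclusion reason per rejected study.

Because clinical cohorts are not shipped, the package includes a kinematic
contracting-ventricle phantom with speckle-textured rendering whose global
and per-segment strains are exact by construction, plus the agreement and
discrimination statistics used to validate automated strain (Bland–Altman
bias and limits, MAD, RMSE, Pearson r, Shapiro–Wilk, Mann–Whitney ROC AUC).

Intended users: researchers developing or validating automated strain
pipelines, and anyone needing a fully synthetic, ground-truthed test bed for
speckle-tracking code.

## Worked example

Generate a zero-noise phantom study (programmed GLS −20%, 70 fps, heart rate
75 bpm, 3 beats), analyse it, and compare with the built-in ground truth:

```r
library(echostrain)

g   <- generate_study("demo", seed = 11, target_gls = -20, heart_rate = 75,
                      frame_rate = 70, n_beats = 3, speckle_noise_sd = 0)
rep <- analyze_study(g$study)

rep$status
#> [1] "analysed"
rep$total_gls
#> [1] -19.86488
head(rep$segments, 3)
#>   view              label peak_strain
#> 1  A4C basal-inferoseptal   -19.55222
#> 2  A4C   mid-inferoseptal   -19.89337
#> 3  A4C      apical-septal   -20.05929
rep$per_view$A4C$checks
#>                    check status                detail
#> 1    view_identification   pass       confidence 1.00
#> 2 measurement_confidence   pass  mean residual 0.0078
#> 3             heart_rate   pass  3/3 cycles in bounds
#> 4           displacement   pass 3/3 cycles within tau
#> 5   systole_diastole_ecg   pass  3/3 cycles congruent
```

The recovered total GLS of −19.86% sits within 0.14 strain-% of the
programmed −20%, every segment peak is within 0.45%, and all five quality
gates pass. `generate_cohort()` scales this to seeded multi-study cohorts
(optionally with akinetic segments), `run_cohort()` produces the per-study
table and exclusion ledger, and `agreement()` / `roc_auc()` compute the
validation statistics against the cohort truth table.

A thin command-line wrapper with `phantom`, `analyze`, `cohort` and
`validate` subcommands is installed at `inst/cli/echostrain`.

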