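Package: echostrain
Title: Automated Left-Ventricular Strain from Apical Echocardiography Contours
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Automated measurement of left-ventricular global and regional
    longitudinal strain from apical-view echocardiographic image sequences and
    per-frame endocardial contour annotations. Tracks the end-diastolic
    endocardial trace through the cardiac cycle with pyramidal Lucas-Kanade
    optical flow stabilized by the per-frame annotations, detects cardiac
    cycles from the cavity-size curve, produces drift-corrected strain curves,
    global longitudinal strain per view and averaged over apical views, and
    peak strain for the six basal/mid/apical segments of the four- and
    two-chamber views (apical cap excluded). Includes sequential quality gates
    (view confidence, measurement confidence, heart rate, trace displacement,
    ECG congruence), agreement and discrimination statistics (Bland-Altman
    bias and limits, MAD, RMSE, Pearson r, Shapiro-Wilk, Mann-Whitney ROC
    AUC), and a kinematic contracting-ventricle phantom with speckle-textured
    rendering and exact ground truth for end-to-end validation without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
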