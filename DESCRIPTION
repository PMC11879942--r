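Package: cmmeivpg
Title: Intraventricular Pressure Gradients and Transmitral Inflow
    Patterns from Color M-Mode Echocardiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating relative intraventricular pressure
    differences and gradients (IVPD/IVPG) from color M-mode
    echocardiographic velocity maps via the one-dimensional Euler
    equation, with a basal / mid-to-apical segmental decomposition;
    classification of transmitral inflow morphology into EA-separation,
    EA-half-separation and EA-fusion; derived diastolic indices (left
    ventricular mass, E/E', estimated LVEDP and pre-A LVDP); a synthetic
    cycle and cohort generator emulating a rat hypertensive-cardiomyopathy
    study design; and the accompanying statistical stage (unbalanced
    two-way ANOVA with Tukey HSD compact letters, Pearson correlations
    against heart rate and the coded inflow pattern).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
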