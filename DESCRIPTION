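Package: diastolica
Title: Invasive Left Ventricular Pressure-Curve Analysis and Biomarker
    Survival Modelling for Diastolic Dysfunction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing invasively recorded left ventricular (LV)
    pressure waveforms and for modelling long-term survival in patients
    evaluated for diastolic dysfunction. Provides a physiologically
    parameterised LV pressure-waveform simulator with analytically known
    derivatives and integrals, cycle segmentation and fiducial detection,
    extraction of LV end-diastolic pressure (LVEDP), dP/dt extrema and
    pressure-time integrals averaged over consecutive end-expiration beats,
    and an LVEDP-based diastolic-dysfunction classification. A companion
    synthetic-cohort generator draws right-skewed serum biomarkers
    (natriuretic peptides, soluble ST2, galectin-3), echocardiographic and
    catheterization covariates, and event times from a Weibull
    proportional-hazards process. The statistical workflow covers
    normality-routed descriptive comparisons, Kaplan-Meier curves with
    median-dichotomized predictors, univariate and multivariable Cox
    regression with forward-stepwise selection by the Bayesian information
    criterion, bootstrap percentile confidence intervals and Harrell's
    C-statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    survival,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
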