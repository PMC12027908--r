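# diastolica

Invasive left-ventricular (LV) pressure-curve analysis and biomarker
survival modelling for patients evaluated for diastolic dysfunction.

Cardiologists assessing diastolic dysfunction combine serum biomarkers
(natriuretic peptides BNP/NT-proBNP/MR-proANP, soluble ST2, galectin-3,
MR-proADM), echocardiography, and — as the gold standard — LV pressures
measured during left heart catheterization. This package provides, for
that setting:

* **Waveform simulation** (`waveform_params()`, `simulate_waveform()`):
  multi-cycle LV pressure traces built from analytic phases with
  closed-form derivatives and integrals, plus Gaussian noise and
  respiratory baseline wander, so every downstream step can be tested
  against known ground truth. Three clinical phenotypes are available as
  presets (`waveform_preset()`).
* **Hemodynamic extraction** (`compute_hemodynamic_params()` and friends):
  cycle segmentation, fiducial detection, Savitzky–Golay-smoothed
  differentiation, and the five derived parameters — LVEDP, LV
  end-systolic pressure, max/min dP/dt, contraction and relaxation
  integrals (areas under the dP/dt curve between fiducials) and the
  diastolic pressure-time integral — averaged over five consecutive
  end-expiration beats, with the LVEDP > 15 mmHg diastolic-dysfunction
  classification.
* **Cohort simulation** (`cohort_config()`, `simulate_cohort()`):
  synthetic patient cohorts with right-skewed biomarker distributions
  solved from published median/IQR anchors, Weibull proportional-hazards
  event times acting on median-dichotomized covariates, and
  uniform-enrollment administrative censoring calibrated to ≈14.5%
  mortality over a ≈1.66-year median follow-up.
* **Survival workflow** (`run_analysis()`): Shapiro–Wilk-routed
  descriptive comparisons, Kaplan–Meier curves per median-dichotomized
  marker, univariate Cox, forward-stepwise multivariable Cox selected by
  BIC (with the number of events as the effective sample size),
  1000-resample bootstrap percentile confidence intervals, and Harrell's
  C-statistic — for a *non-invasive* scenario (clinical + serum + echo
  covariates) and an *invasive* scenario (adding catheterization
  parameters).

The central identity used throughout: by the fundamental theorem of
calculus, the contraction integral ∫ (dP/dt) dt from end-diastole to peak
systole equals P_peak − P_ed, and the relaxation integral equals
P_peak − P_es. For the default waveform (P_ed = 12, P_peak = 170 mmHg)
the contraction integral is therefore exactly 158 mmHg, and the dP/dt
extrema are ±(ΔP·π)/(2·duration): ≈1838 and ≈−1984 mmHg/s.

## Worked example

```r
library(diastolica)

## 1. Noiseless default waveform -> extraction recovers the analytic truth
sim <- simulate_waveform(waveform_params(noise_sd = 0, resp_amplitude = 0))
compute_hemodynamic_params(sim$waveform)
#> Hemodynamic parameters (mean of 5 end-expiration cycles)
#>   LVEDP                    12.4 mmHg   (diastolic dysfunction: no)
#>   LV end-systolic P         2.0 mmHg
#>   max dP/dt                1838 mmHg/s
#>   min dP/dt               -1984 mmHg/s
#>   contraction integral    157.6 mmHg
#>   relaxation integral     168.0 mmHg
#>   diastolic integral       4.17 mmHg*s

## 2. Synthetic cohort, invasive-scenario survival analysis
co <- simulate_cohort(cohort_config(n = 500, seed = 42))
summarize_cohort(co)
#> n = 500 patients; 76 deaths (15.2%), 34 within year 1 (6.8%)
#> median follow-up 1.65 (1.14-2.18) years
#> diastolic dysfunction (LVEDP > 15 mmHg): 167 (33.4%)

report <- run_analysis(co, scenario_config("invasive", seed = 1))
report
#> == invasive scenario ==
#> ...
#> Final multivariable Cox model (bootstrap 95% CI):
#>                   variable cutoff   hr ci_lower ci_upper p_value
#> 1            e_over_eprime   10.1 2.27     1.42     3.75 0.00073
#> 2          nt_probnp_pg_ml   86.8 2.01     1.23     3.29 0.00400
#> 3 relaxation_integral_mmhg  140.0 0.54     0.33     0.84 0.00840
#>
#> C-statistic: 0.659
```

Reading the output: the extractor reproduces the simulator's closed-form
anchors (contraction integral 157.6 vs the analytic 158 mmHg; dP/dt
extrema within 0.1%; the ~0.4 mmHg LVEDP offset is the documented
slope-threshold bias of the end-diastole definition). In the cohort run,
markers the generator made prognostic (E/E′ > 9.8-ish cut-off, NT-proBNP)
enter the stepwise model with hazard ratios near their generating values,
and the C-statistic quantifies the discrimination of the selected model.
`write_model_report()` exports the report as JSON plus per-stratum
Kaplan–Meier CSVs; a thin command-line wrapper is installed at
`inst/scripts/diastolica`.

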