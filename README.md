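# twamap

Hypotension exposure during cardiopulmonary bypass and cardiac
surgery-associated acute kidney injury: a tested, reusable analysis
pipeline.

## The problem

Acute kidney injury (AKI) complicates 20–40% of cardiac surgeries.
Whether mean arterial pressure (MAP) below 65 mmHg *during
cardiopulmonary bypass (CPB)* — a period of nonpulsatile flow and altered
hemodynamics — is associated with postoperative AKI has been
controversial. This package implements the full analysis chain for that
question on INSPIRE-style relational perioperative data (vitals,
operations, labs, patients as long/wide CSV tables), for
anesthesiology/ICU researchers who want the exposure metric, the outcome
adjudication and the models as auditable, tested code rather than a
one-off script.

## The statistic at its core

The exposure is the time-weighted average depth of MAP below a threshold
$T$ over the CPB window $[t_0, t_1]$:

$$\mathrm{TWA}_{<T} = \frac{\mathrm{AUC}_{<T}}{t_1 - t_0}, \qquad
\mathrm{AUC}_{<T} = \int_{t_0}^{t_1} \max\{0,\, T - \mathrm{MAP}(t)\}\,dt,$$

computed by the composite trapezoidal rule on the piecewise-linear
interpolant of irregularly sampled invasive MAP (threshold crossings
inserted exactly, by default). $T = 65$ mmHg primary, 75 mmHg as
sensitivity. The outcome is KDIGO creatinine-criteria AKI (all stages,
7-day horizon) and postoperative CRRT; the association is estimated as an
adjusted odds ratio per mmHg from multivariable logistic regression over
a 21-covariate clinical adjustment set (`model_covariates()`), with
rank-sum descriptive comparisons, delta-method predicted-probability
curves, a 75-mmHg sensitivity analysis and a hypertension subgroup
analysis.

A synthetic-cohort generator (`simulate_cohort()`) emits the same four
tables with known ground truth (true exposure log-odds ln 1.07 for AKI,
ln 1.05 for CRRT; 34% / 10% marginal incidence), so the entire pipeline
is testable without any data download.

## Worked example

```r
library(twamap)

# a 10-minute window where MAP dips 70 -> 60 -> 70 across the 65 line
tri <- map_series("demo", c(0, 300, 600), c(70, 60, 70))
twa_below(tri, analysis_window("cpb", 0, 600))
#> <exposure_summary> T=65 mmHg: AUC 12.50 mmHg*min, TWA 1.250 mmHg,
#>   5.0/10.0 min below, 3 samples, max gap 5.00 min
```

The AUC is the 12.5 mmHg·min triangle between the crossings at minutes
2.5 and 7.5; dividing by the 10-minute window gives a TWA of 1.25 mmHg.

End to end on a synthetic cohort:

```r
sim <- simulate_cohort(sim_config(n_patients = 1000, seed = 2026))
res <- run_cohort_pipeline(sim$vitals, sim$operations, sim$labs, sim$patients)
str(res$attrition)
#> List of 6
#>  $ n_input                : int 1000
#>  $ n_eligible             : int 941
#>  $ insufficient_resolution: int 20
#>  $ invalid_cpb_window     : int 9
#>  $ no_cpb                 : int 25
#>  $ missing_covariates     : int 5

bundle <- run_analysis_suite(res$cohort)
print(bundle$table_s2, digits = 3)
#>            model   n n_events   or ci_lo ci_hi        p converged
#> 2      aki_crude 941      300 1.08 1.049  1.11 3.71e-07      TRUE
#> 21  aki_adjusted 941      300 1.08 1.050  1.12 1.20e-06      TRUE
#> 22    crrt_crude 941      104 1.02 0.988  1.06 1.99e-01      TRUE
#> 23 crrt_adjusted 941      104 1.01 0.971  1.05 6.52e-01      TRUE
```

Every input operation lands either in the cohort or in a named attrition
bucket. The adjusted AKI odds ratio of 1.08 per mmHg recovers the
generator's true 1.07 within sampling error at n = 941 (the acceptance
suite verifies mean recovery to ±0.01 and 92–98% CI coverage over 500
cohorts of n = 2,352); the CRRT model, with a weaker true effect (1.05)
and only 104 events, is compatible with that effect but not significant
at this sample size. The bundle also carries the descriptive table
(`table_s1`), the 75-mmHg sensitivity (`table_s3`), the hypertension
subgroups (`table_s4`), the predicted-probability curve (`prob_curve`)
and all fit objects; `run_analysis_suite(cohort, out_dir = "out/")`
writes CSVs, a JSON model dump and the two figures.

A command-line interface covers the same flow
(`exec/twamap simulate|build-cohort|analyze`), configured by YAML
(`inst/extdata/config-example.yaml`).

## Scope

No waveform-level signal processing, no urine-output KDIGO criteria, no
causal-inference machinery, no EuroSCORE II computation (consumed as a
covariate). See `vignettes/twamap-methods.Rmd` for the model, the
synthetic-data design, numerical choices, and known limitations.
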