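---
title: "Hypotension exposure during cardiopulmonary bypass and postoperative kidney injury: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{twamap methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the estimand

Acute kidney injury complicates 20–40% of cardiac surgeries, and the
cardiopulmonary bypass (CPB) phase — nonpulsatile flow, altered
hemodynamics, reduced oxygen delivery — is a plausible window of renal
vulnerability. `twamap` implements a retrospective cohort analysis of the
association between intraoperative hypotension during CPB and cardiac
surgery-associated acute kidney injury (CSA-AKI), with postoperative
continuous renal replacement therapy (CRRT) as a secondary outcome.

The exposure is the *time-weighted average MAP below a threshold*:

$$\mathrm{TWA}_{<T} \;=\; \frac{1}{t_1 - t_0}\int_{t_0}^{t_1} \max\{0,\; T - \mathrm{MAP}(t)\}\, dt,$$

with $T = 65$ mmHg and $[t_0, t_1]$ the CPB run. The integral (the "area
under the threshold", mmHg·min) is evaluated by the composite trapezoidal
rule on the piecewise-linear interpolant of the irregularly sampled
invasive MAP; dividing by the window duration gives a severity-and-duration
summary in mmHg. The association estimand is the adjusted odds ratio for
the outcome per 1 mmHg of $\mathrm{TWA}_{<65}$ from a multivariable
logistic regression.

## Exposure computation

Two numerical readings of "the area between the threshold and the MAP
measurements" are possible, and both are implemented behind the
`interpolate_crossings` flag of `deficit_auc()`:

* **Crossing-interpolated (default).** The exact points where the linear
  MAP segments cross $T$ are inserted before the trapezoid is applied to
  the clipped deficit $d(t) = \max(0, T - \mathrm{MAP}(t))$. This is exact
  for the piecewise-linear curve.
* **Sample-clipped.** The trapezoid is applied to the clipped deficits at
  the sample points only. This overestimates the area of partial
  excursions (a segment from 70 to 60 mmHg contributes a trapezoid on
  deficits $(0, 5)$ rather than the true triangle).

Window edges are handled by linearly interpolating MAP onto $t_0$ and
$t_1$ from straddling samples; samples outside the window are never
integrated. The denominator is always the *full* window duration — "total
CPB time" — even if samples do not quite reach the edges; the eligibility
rule below bounds how much can be missing.

Eligibility requires invasive MAP at five-minute resolution or better:
`resolution_check()` passes iff no inter-sample gap inside the window
(edge gaps included, boundary inclusive) exceeds 5 minutes. Patients
failing the check are excluded rather than imputed, so `deficit_auc()`
never has to decide what happened inside a long gap.

Artifact handling is a plausibility window (default 10–200 mmHg,
configurable) plus averaging of duplicate timestamps. The source analysis
does not state its artifact rules; ours are explicit configuration, not a
claim about the original study.

## Outcome adjudication

CSA-AKI is adjudicated by the KDIGO serum-creatinine criteria (all
stages) within 7 days of surgery; urine-output criteria are excluded by
construction. Entry requires a rise of ≥ 0.3 mg/dL within a rolling 48-h
window or ≥ 1.5× baseline within the horizon; stages 1/2/3 correspond to
1.5–1.9× (or the 0.3 mg/dL rise), 2.0–2.9×, and ≥ 3.0× — with stage 3
also granted for creatinine ≥ 4.0 mg/dL *alongside a qualifying acute
rise* (guarding against chronic elevation) or for renal replacement
therapy within the horizon.

Two readings of the 48-h criterion exist; we evaluate it against **all**
anchor measurements (baseline and every prior postoperative value), not
only baseline. This matches the criterion's "within 48 hours" text and is
the conservative reading: a slow creep that rises 0.4 mg/dL across a
48-hour span between two measured values is AKI.

The baseline creatinine definition is not stated by the source analysis;
the default policy is the most recent value within 7 days before surgery,
with minimum-within-7-days and most-recent-within-30-days as alternatives.
Patients with no qualifying baseline are excluded with an attrition
reason; an empty postoperative series yields stage 0 with a logged flag.
The CRRT secondary outcome is the hospital-stay CRRT indicator as-is (no
7-day horizon); only the RRT flag *inside* the adjudication horizon
forces stage 3, which is why the pipeline consumes an optional
`crrt_start_day` column.

## Models

Group comparisons use the Wilcoxon–Mann–Whitney rank-sum test: exact
enumeration of the null distribution of $U$ when both groups have ≤ 10
observations, otherwise the normal approximation with tie correction and
continuity correction.

Logistic regressions are fitted by IRLS (relative deviance change
< 1e-8, ≤ 100 iterations). Confidence intervals are Wald,
$\exp(\hat\beta \pm 1.96\,\mathrm{SE})$, matching the conventional
reporting of adjusted odds ratios; degenerate outcomes, rank-deficient
designs and (quasi-)separation are surfaced as errors or flags, never as
silently odd numbers. Categorical covariates use reference-cell dummy
coding with the reference fixed as the alphabetically first level, so
results are invariant to row order. The adjusted covariate set is the
clinical-plausibility list returned by `model_covariates()`: age, sex,
weight, surgery type, emergency status, ASA status, eGFR strata at
admission, EuroSCORE II, five comorbidities, three preoperative drug
classes, total vasopressor-inotrope dose, fluid balance, post-CPB
TWA-MAP under 65 mmHg, CPB time, and pRBC units. Continuous covariates
enter linearly (no splines — the functional form the source analysis
implies by reporting a single per-mmHg odds ratio).

Predicted-probability curves use the delta method on the linear
predictor, transformed through the inverse logit so the band stays inside
$[0,1]$. The covariate profile holds continuous covariates at their
cohort means and categoricals at reference levels; this profile is a
package choice (the source figure does not state one) and is overridable.

Sensitivity analyses follow the same structure: a 75-mmHg threshold
variant with exposures recomputed at 75 mmHg (keeping the 65-mmHg
post-CPB covariate would double-count, so the 75-mmHg models drop it),
and a hypertension subgroup analysis with the hypertension covariate
removed from the adjustment set. No multiplicity adjustment is applied;
the analyses are labeled exploratory.

## The synthetic cohort: what it emulates, and what a green test means

`simulate_cohort()` generates the four relational tables the readers
consume — vitals, operations, labs, patients — with known ground truth:

* **Outcome-first design.** AKI and CRRT are drawn from true logistic
  models on the drawn TWA exposure (effects ln 1.07 and ln 1.05 per mmHg)
  and the covariates, with intercepts calibrated by root-finding so the
  marginal incidences hit 34% and 10% given the simulated covariate
  distribution. The MAP path is then constructed to *realize* the drawn
  TWA: an Ornstein–Uhlenbeck walk (SD 8 mmHg, 5-min mean-reversion
  timescale, 60 ± 30 s sampling truncated at 5 min) whose CPB-regime mean
  is adjusted by bisection until the realized TWA is within 0.1 mmHg of
  target. Generating the outcome from the exposure directly — rather than
  from the raw path — keeps parameter-recovery tests sharp: the true
  coefficient is exact, not itself an estimate.
* **Exposure distribution.** TWA under 65 is lognormal with median
  2.5 mmHg and log-SD 1.0, chosen to bracket the interquartile ranges the
  study reports (roughly 0.7–6.5 mmHg across outcome groups), mildly
  shifted by illness-severity covariates so that confounding is real and
  adjustment matters.
* **Creatinine trajectories** are built to adjudicate to the assigned
  stage: a peak-ratio draw inside the stage band (1.55–1.90, 2.10–2.85,
  3.10–4.50), a rise to a peak at day 2–4, partial recovery by day 7, and
  a deliberately out-of-horizon sample at day 10. Non-AKI patients get
  multiplicative noise small enough never to trip a criterion.
  Construction-versus-adjudicator agreement is a tested invariant.
* **Engineered attrition.** Configurable fractions of operations lack CPB
  events, have an inverted CPB window, or contain a 7-minute sampling
  hole mid-CPB, exercising every exclusion reason.

What the generator does **not** emulate: real arterial-line artifacts
beyond range violations, inter-covariate correlation structure beyond the
configured confounding shifts, informative lab-sampling frequency (sicker
patients are drawn more often in reality), competing risks of death, and
the measured-TWA error structure of one-second waveform data. A green
recovery test therefore establishes that the pipeline estimates without
bias *under its own assumptions* — it does not validate the causal claim,
nor reproduce the public-registry numbers, which would require the actual
download-scale dataset.

## Numerical choices

* All internal times are seconds from surgery start (double precision);
  readers shift absolute per-patient-clock timestamps using the
  operations table. AUC is reported in mmHg·min, TWA in mmHg.
* Creatinine unit conversion is µmol/L ÷ 88.4; unknown unit labels are a
  hard error.
* KDIGO threshold comparisons carry a 1e-12 absolute guard so that
  floating-point ties at criterion boundaries (e.g. a value exactly 1.5×
  baseline) resolve to the mathematical comparison.
* The oracle used to validate the exposure integral is a dense midpoint
  Riemann sum with cells at most 0.01 min wide aligned to the sample
  breakpoints. Alignment matters: with cells straddling kinks, the
  discretization error of *any* fixed 0.01-min grid exceeds the 1e-3
  mmHg·min validation tolerance once adjacent samples are allowed to jump
  tens of mmHg, because crossing-cell errors share a sign. Validation
  fixtures therefore use physiologically plausible slew rates (a slow
  random walk at ≥ 45 s spacing), where the measured worst error over
  1,000 series is below 3e-4.
* The rank-sum exact branch enumerates all $\binom{n_1+n_2}{n_1}$
  assignments of the pooled (tied) ranks; with both groups of size 10
  that is 184,756 combinations, the practical ceiling.
* Duplicate vitals timestamps are averaged (order-independent, unbiased);
  the alternative (keep-first) would make results depend on file order.

## Known limitations

* Whether the original analysis interpolated threshold crossings, and
  whether "total CPB time" excludes intra-CPB gaps, are unstated; the
  defaults here (interpolate; full duration) are flagged configuration.
* One operation per patient (the first qualifying surgery) avoids
  correlated observations at the cost of discarding reoperation data.
* Complete-case covariate handling is the default; median/mode imputation
  exists for robustness runs but no multiple imputation.
* The eGFR helper implements CKD-EPI 2009 (race-free usage) with strata
  cutpoints 90/60/45/30/15 — an assumption, used only when the source
  tables ship creatinine without a precomputed stratum.
* Total vasopressor-inotrope dose aggregation uses an explicit
  norepinephrine-equivalence weight table; no standard is mandated by the
  data source, so the weights are configuration, not science.
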