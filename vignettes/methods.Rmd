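---
title: "Methods: dietary mercury exposure assessment for a fish-meal intervention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary mercury exposure assessment for a fish-meal intervention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgexposure)
```

## The exposure model

The package implements deterministic intake arithmetic, the standard
point-estimate approach for a short, fully prescribed dietary
intervention. For a meal of mass $m$ (kg) of fish with tissue
concentration $c$ (mg THg/kg wet weight), the mercury intake is

$$ I = 1000 \, c \, m \quad [\mu g], $$

and over a meal schedule the total is the sum over meals. Rates are

$$ \mathrm{EDI} = \frac{\sum I}{d \cdot bw}, \qquad
   \mathrm{EWI} = \frac{\sum I}{w \cdot bw}, $$

with $d$ the number of fish-consumption days, $w$ the number of calendar
weeks, and $bw$ the body weight in kg. Risk is characterised by the
hazard index $\mathrm{HI} = \mathrm{EWI}/\mathrm{PTWI}$ and its
percentage form. Two divisor conventions deserve note:

- **Daily intake divides by consumption days**, not calendar days: a
  105 µg total over 10 eating days is reported as 10.5 µg/day. The
  calendar-day alternative (divide by 14) is available via
  `daily_intake(..., per = "calendar")`.
- **Weekly intake divides the total by the number of weeks** (two for
  the intervention template). A sliding 7-consecutive-day window is not
  implemented; for schedules with meals every calendar day the two
  agree.

All computation is carried at full floating precision; rounding (or, for
one reported quantity, truncation — see `trunc_to()`) happens only when
values are printed. One consequence worth knowing: the fixtures-only EWI
for a 70 kg subject is $52.606/70 = 0.7515$, which rounds to 0.752 at
three decimals, whereas rounding the weekly total to 52.6 first would
give 0.751. The package never rounds intermediates.

### Assumptions

- THg measured in fish muscle is treated as MeHg for PTWI comparison
  (`mehg_fraction = 1.0` in `default_thresholds()`). This is the
  conservative convention for headline risk figures; the common
  literature alternative 0.9 is available as a parameter and scales all
  downstream risk metrics linearly.
- Concentrations are state-specific: the intervention consumed fried
  fish, so fried-state means drive the worked example; scenario
  functions take the concentration as an explicit argument.
- Exceedance of a limit uses strict `>` by default, so a subject exactly
  at the limit counts as compliant; `strict = TRUE` flips the boundary.

## Regulatory thresholds

| quantity | default | units | meaning |
|---|---|---|---|
| `ptwi_mehg` | 1.6 | µg/kg bw/week | JECFA PTWI for MeHg |
| `ptwi_thg` | 4.0 | µg/kg bw/week | PTWI for total Hg |
| `nrc_limit` | 0.7 | µg/kg bw/week | US-NRC weekly limit |
| `mpc` | 0.5 | mg/kg wet wt | EC 1881/2006 limit for most fish |
| `ptwi_japan` | 3.4 | µg/kg bw/week | PTWI applied in Japan |
| `mehg_fraction` | 1.0 | — | assumed MeHg share of THg |

## Descriptive statistics conventions

- The 95th percentile uses linear interpolation between closest ranks
  (`stats::quantile` type 7, R's default). The reference table's P95
  values were produced from raw measurements that are not available, so
  the convention is fixed here and verified against an independent
  sort-and-interpolate oracle in the tests rather than matched to the
  printed table.
- SDs are sample ($n-1$) SDs; with 12 measurements per species/state the
  distinction is small but a convention had to be chosen.
- The raw-vs-fried "percent" notation reported for these species is
  numerically the absolute mg/kg difference × 100 (0.060 − 0.049 =
  0.011 → "1.1%"), not a relative change. `raw_fried_difference()`
  reproduces it under the clearly-labelled name `reported_pct` alongside
  the conventional `rel_pct`; the package does not arbitrate which the
  original authors intended.
- MPC compliance compares the species *mean* against the limit
  (inclusive boundary); a strict mode compares the per-sample maximum.

## The synthetic-data generator

No per-subject data were published, so the generator emulates the study
conditions and is itself first-class, tested code. It is calibrated
once, to the published population statistics, and its defaults are the
study conditions — they are not tuning knobs.

**Cohort.** BMI is truncated-normal on [17.8, 40.2] kg/m² with target
mean 26.9 and SD 4.3. Because truncating a normal shifts its moments,
the generator first solves for the underlying location and scale such
that the *truncated* distribution has the target mean and SD
(closed-form truncated-normal moments, numeric optimisation); draws are
then by rejection. Height is normal 1.77 ± 0.07 m — an assumed input,
since the study reports BMI only. It was chosen once so that mean body
weight $BMI \times h^2$ lands near 85 kg, the value consistent with the
published weekly intake rates (52.6 µg/week ÷ 0.62 µg/kg/week ≈ 85 kg);
that back-derivation is an inference of ours, not a published datum.
Smoking (21%) and amalgam (34%, 1–5 fillings) are Bernoulli covariates
used only for descriptive group summaries.

**Tissue concentrations.** Lognormal — positive and right-skewed, the
usual shape for contaminant residues — truncated to each group's
published range, again with underlying parameters calibrated so the
truncated distribution reproduces the target mean, and the SD as nearly
as the range permits. For some groups the published range is too narrow
to contain the published SD at all (e.g. fried *P. virens*: SD 0.019
over a range of width 0.055, whereas even a uniform on that range has SD
0.016); there the calibration prioritises the mean (weighted 25:1) and
accepts the closest achievable SD, and it also refuses parameter regions
holding < 5% of the probability mass between the bounds, which would be
degenerate edge-piled shapes and intractable for rejection sampling.

**Meal schedule.** The `intervention_2015` template: fried fish on days
1–3 (hoki), 4–5 (pollock), 8–10 (cod), 11–12 (coalfish), at the fried
portion-mass means; 10 consumption days over 2 weeks, total mass
1.595 kg ("approximately 1.6 kg").

**Biomarkers.** Explicitly a *calibration device, not a toxicokinetic
model* — the study fitted none, and inventing one would misrepresent
provenance. Baseline blood is truncated-normal (≥ 0) at 0.62 ± 0.41
µg/l; blood at the intermediate and final timepoints adds an uptake term
proportional to the subject's cumulative intake per kg body weight, with
lognormal mean-1 noise (CV 0.4, chosen to put the day-10 blood SD at the
reported order); the proportionality constants are calibrated within the
run so the population means hit 0.90 and 1.28 µg/l. The one-month value
relaxes a calibrated fraction of the way back toward baseline (target
mean 0.78). Hair at baseline is truncated-normal 0.24 ± 0.16 µg/g; hair
at one month is the configured ratio (0.23) times the subject's day-10
blood with lognormal noise (CV 0.3 — a free parameter, since the
per-subject dispersion of the ratio is unknowable from published
summaries; 0.3 reproduces the order of magnitude of the published ratio
range). A zero-intake schedule with zero noise leaves all blood
timepoints at baseline, which the tests assert.

**Determinism.** One global seed fans out to fixed per-component
substreams, so generating fish samples before or after the cohort never
perturbs the cohort's draws; identical configs give identical output.

### What the generator does and does not show

Passing parameter-recovery tests shows the pipeline correctly measures
what the generator put in (means within 3 standard errors at the study
size n = 67 and at n = 10 000, exceedance matching the analytic quantile
of the generating body-weight distribution). It does *not* show the
synthetic data reproduce the real cohort's joint structure: real
covariance between body weight and intake behaviour, non-lognormal
concentration shapes, hair growth kinetics, or measurement error are all
absent. Quantities that depend on the unavailable per-subject data —
the published EWI range, the 32.8% NRC exceedance, the exact biomarker
SDs — are therefore recovered only approximately, and the package makes
no claim to reproduce them exactly.

## Hair-to-blood ratio conventions

The ratio is computed in the matrices' native units, µg/g over µg/l, the
convention under which the cohort mean is ~0.23 (the textbook ~250:1
ratio uses matched mass units and differs by the factor 1000 and blood
density). "Average ratio" is read as the mean of per-subject ratios —
consistent with a per-subject distribution having a median, P95 and
range — with ratio-of-means available as an alternative. Pairing for
both the ratio and the OLS fit follows the collection design: hair taken
one month after the study (T4) against blood taken at the end of
exposure (T3), reflecting the lag before exposed hair emerges.

## Numerical and degenerate-input choices

- Single-sample groups have `sd = NA` (undefined), not 0.
- Empty schedules total 0 µg; a schedule with zero consumption days
  cannot produce a daily intake (error).
- `max_allowable_weekly_mass()` with zero concentration has no finite
  bound and errors rather than returning `Inf`.
- `linear_fit()` refuses a constant predictor ("zero variance in
  predictor"); a constant response returns `r = 0`.
- Readers validate schemas and units up front: missing columns are named,
  negative masses/concentrations are rejected with their row number,
  hair records outside T1/T4 are rejected.

## Problem sizes

The test suite and acceptance script use the study-sized cohort
(n = 67) for recovery checks, n = 10 000 for tight moment checks on the
cohort generator, 12 samples per species/state (the study's count) for
end-to-end runs, and n = 20 000 lognormal body weights for the analytic
exceedance comparison. The full suite completes in well under a minute
on one CPU.

## Known limitations

- No probabilistic (2-D) uncertainty/variability separation; the
  exposure model is a point-estimate calculation by design.
- No toxicokinetic intake-to-blood conversion; the biomarker generator
  is calibrated, not mechanistic.
- Literature comparison values (`literature_intakes()`) are shipped as
  documented constants only; their inputs are not available to recompute.
- Hypothesis testing across timepoints or covariate groups is
  deliberately out of scope: on synthetic data the p-values would be
  artefacts of generator choices, so the biomarker module stays
  descriptive.
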