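# hgexposure

Dietary methylmercury exposure assessment for fish-meal intervention
studies.

## What this is for

Fish is the dominant dietary source of methylmercury (MeHg), a
neurotoxicant that bioaccumulates up the marine food chain. Risk
assessors characterise consumer exposure by combining measured total
mercury (THg) concentrations in fish tissue with consumption amounts,
normalising by body weight, and comparing the resulting intake rates to
regulatory limits: the JECFA provisional tolerable weekly intake (PTWI,
1.6 µg MeHg/kg bw/week), the stricter US-NRC weekly limit (0.7 µg/kg
bw/week), and the EC maximum permitted concentration in food (MPC, 0.5
mg/kg wet weight).

`hgexposure` implements that workflow end to end for intervention-style
studies in which a cohort eats a prescribed fish menu over consecutive
weeks while blood and hair mercury are monitored:

- **Fish tissue summaries** — per-species descriptive statistics (mean,
  SD, median, P95, range) by preparation state (raw/fried), raw-vs-fried
  comparison, MPC compliance, and analyser QC limits (detection limit =
  3 blank SD, quantification limit = 6 blank SD).
- **Exposure engine** — per-meal intake `conc × mass × 1000` (µg), totals
  over a meal schedule, estimated daily/weekly intake (EDI/EWI in µg/kg
  bw), percent of PTWI, hazard index `HI = EWI / PTWI`, and cohort
  exceedance fractions.
- **Scenarios** — reference-consumer projections (e.g. three 150 g meals
  a week for a 70 kg person), single-species weeks, and the inverse
  problem: the maximum fish mass consumable per week under a given limit.
- **Biomarkers** — longitudinal blood (µg/l) and hair (µg/g) THg
  summaries across four timepoints, per-subject hair-to-blood ratios, and
  the hair-on-blood OLS fit.
- **Synthetic data** — a seeded generator that emulates the study
  conditions (cohort anthropometry from BMI 26.9 ± 4.3 kg/m², the
  10-consumption-day/2-week menu of four Gadiformes species, lognormal
  tissue concentrations matching the reference table, and biomarker
  trajectories calibrated to the published timepoint means), so the whole
  pipeline is testable without per-subject study data, which were never
  published.

## Worked example

The canonical worked example is the intervention menu itself: fried fish
on 10 days over 2 weeks (3 days *Macruronus magellanicus* and 2 days
*Gadus chalcogrammus*, then 3 days *Gadus morhua* and 2 days *Pollachius
virens*), at the fried mean concentrations and portion masses of the
reference table.

```r
library(hgexposure)

sched <- generate_meal_schedule()           # the intervention menu
conc  <- conc_table(subset(fish_reference(), state == "fried"))

total <- schedule_total_intake(sched, conc)
total                                       # 105.212 ug over the study
daily_intake(total, sched)                  # 10.5212 ug per eating day
weekly <- weekly_intake(total, sched)       # 52.606 ug/week

ewi(weekly, 70)                             # 0.7515 ug/kg bw/week at 70 kg
hazard_index(0.62, 1.6)                     # 0.3875 for the cohort-mean EWI
reference_person_weekly(0.109, 0.150, 3, 70)  # 0.7007: 3 hoki meals/week
single_species_week(0.109, 0.150, 7, 85.4)    # 1.3402: an all-hoki week
max_allowable_weekly_mass(0.109, 1.6, 70)     # 1.028 kg of hoki per week
```

A full synthetic study, through the pipeline:

```r
study <- simulate_study(generator_config(seed = 601))
rep <- run_pipeline(study$fish_samples, study$schedule, study$cohort,
                    biomarkers = study$biomarkers)
rep$exposure$summary$ewi$mean     # ~0.62 ug/kg bw/week
rep$exposure$exceedance$nrc      # fraction above the US-NRC 0.7 limit
rep$biomarker$ratio$mean          # hair/blood ratio, ~0.23
```

The numbered scripts under `analysis/` run these stages as a narrative
workflow (`01_simulate` → `05_biomarkers`), writing tables under
`results/`.

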