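#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# No per-subject data were published for the intervention, so every
# downstream stage runs on a seeded synthetic cohort of 67 men calibrated
# to the published population statistics (BMI 26.9 +/- 4.3, 21% smokers,
# 34% with amalgam fillings), twelve tissue samples per species/state
# matching the reference concentration table, the 10-consumption-day
# /2-week meal schedule, and blood/hair trajectories calibrated to the
# published timepoint means.

suppressPackageStartupMessages(library(hgexposure))

seed <- 20150601 %% 100000  # study recruitment began June 2015
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

study <- simulate_study(generator_config(seed = seed))

write_table(study$cohort, file.path(out, "cohort.csv"))
write_table(study$fish_samples, file.path(out, "fish_samples.csv"))
write_table(study$schedule$events, file.path(out, "meals.csv"))
write_table(study$biomarkers, file.path(out, "biomarkers.csv"))

message(sprintf("cohort: n = %d, BMI %.1f +/- %.1f, body weight %.1f +/- %.1f kg",
                nrow(study$cohort), mean(study$cohort$bmi), sd(study$cohort$bmi),
                mean(study$cohort$body_weight_kg), sd(study$cohort$body_weight_kg)))
message(sprintf("fish samples: %d rows; schedule: %d meals on %d days; biomarkers: %d records",
                nrow(study$fish_samples), nrow(study$schedule$events),
                study$schedule$consumption_days, nrow(study$biomarkers)))
message("wrote ", out, "/{cohort,fish_samples,meals,biomarkers}.csv")
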