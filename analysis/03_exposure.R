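#!/usr/bin/env Rscript
# Stage 3: intake arithmetic and risk characterisation.
#
# First the deterministic worked example from the reference concentration
# table (the study's own headline numbers), then the per-subject exposure
# distribution over the synthetic cohort.

suppressPackageStartupMessages(library(hgexposure))

thresholds <- default_thresholds()
sched <- generate_meal_schedule()
ref_conc <- conc_table(subset(fish_reference(), state == "fried"))

total <- schedule_total_intake(sched, ref_conc)
message(sprintf("reference intake over the intervention: %.1f ug (%.0f to the integer)",
                total, round(total)))
message(sprintf("  daily %.2f ug over %d eating days; weekly %.1f ug",
                daily_intake(total, sched), sched$consumption_days,
                weekly_intake(total, sched)))
message(sprintf("  single hoki portion: %.2f ug", meal_intake(0.109, 0.150)))

cohort <- read_cohort("results/synthetic/cohort.csv")
meals <- read_meals("results/synthetic/meals.csv")
samples <- read_fish_samples("results/synthetic/fish_samples.csv")
conc <- conc_table(summarize_fish(samples))

expo <- cohort_exposure(cohort, meals, conc, thresholds = thresholds)
write_table(expo$results, "results/exposure.csv")
jsonlite::write_json(list(summary = expo$summary, exceedance = expo$exceedance),
                     "results/exposure_summary.json", auto_unbox = TRUE, digits = NA)

s <- expo$summary$ewi
message(sprintf("synthetic cohort EWI: mean %.2f, median %.2f, p95 %.2f, range %.2f-%.2f ug/kg bw/week",
                s$mean, s$median, s$p95, s$min, s$max))
message(sprintf("  %% of PTWI: mean %.1f%%; hazard index %.2f",
                expo$summary$pct_ptwi$mean, s$mean / thresholds$ptwi_mehg))
message(sprintf("  exceeding PTWI (%.1f): %.1f%%; exceeding US-NRC (%.1f): %.1f%%",
                thresholds$ptwi_mehg, 100 * expo$exceedance$ptwi,
                thresholds$nrc_limit, 100 * expo$exceedance$nrc))
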