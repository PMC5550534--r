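#!/usr/bin/env Rscript
# Stage 4: projected exposure under hypothetical consumption patterns.

suppressPackageStartupMessages(library(hgexposure))

thresholds <- default_thresholds()
fried <- subset(fish_reference(), state == "fried")
dir.create("results", showWarnings = FALSE)

# a 70 kg reference consumer: 3 weekly meals of the week-1/2 "staple"
# species, 2 of the others, at their fried portion masses
meals_per_week <- c(M_magellanicus = 3, G_chalcogrammus = 2, G_morhua = 3, P_virens = 2)
scen <- do.call(rbind, lapply(fried$species_id, function(sp) {
  row <- fried[fried$species_id == sp, ]
  e <- reference_person_weekly(row$mean, row$portion_mass_mean,
                               meals_per_week[[sp]], 70)
  data.frame(species_id = sp, meals_per_week = meals_per_week[[sp]],
             portion_kg = row$portion_mass_mean,
             ewi_ug_per_kg_week = e,
             pct_ptwi = percent_ptwi(e, thresholds$ptwi_mehg),
             max_allowable_kg_week = max_allowable_weekly_mass(
               row$mean, thresholds$ptwi_mehg, 70))
}))
write_table(scen, "results/scenarios.csv")
message("reference-person weekly intake (70 kg):")
print(scen, digits = 3, row.names = FALSE)

# the worst case: only the highest-Hg species, every day for a week,
# at the inferred cohort mean body weight
e_week <- single_species_week(0.109, 0.150, 7, 85.4)
message(sprintf("all-hoki week at 85.4 kg: EWI %.2f ug/kg bw (%.0f%% of PTWI)",
                e_week, percent_ptwi(e_week, thresholds$ptwi_mehg)))
message(sprintf("PTWI as weekly mass for 70 kg: %.3f mg; the cohort-mean EWI: %.2f mg",
                weekly_mass_equivalent(thresholds$ptwi_mehg, 70),
                weekly_mass_equivalent(0.62, 70)))
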