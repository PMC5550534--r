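#!/usr/bin/env Rscript
# Stage 5: longitudinal blood/hair biomarker summaries, the hair-to-blood
# ratio distribution, and the hair-on-blood linear fit.

suppressPackageStartupMessages(library(hgexposure))

bm <- read_biomarkers("results/synthetic/biomarkers.csv")

grid <- rbind(expand.grid(matrix = "blood", timepoint = c("T1", "T2", "T3", "T4"),
                          stringsAsFactors = FALSE),
              expand.grid(matrix = "hair", timepoint = c("T1", "T4"),
                          stringsAsFactors = FALSE))
tp <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
  s <- timepoint_summary(bm, grid$matrix[i], grid$timepoint[i])
  cbind(grid[i, ], s[, c("n", "mean", "sd")])
}))
write_table(tp, "results/biomarker_timepoints.csv")
message("biomarker timepoint summaries (blood ug/l, hair ug/g):")
print(tp, digits = 3, row.names = FALSE)

paired <- pair_hair_blood(bm)                     # hair T4 against blood T3
rs <- ratio_summary(paired)
message(sprintf("hair/blood ratio: mean %.2f, median %.2f, p95 %.2f, range %.3f-%.3f",
                rs$mean, rs$median, rs$p95, rs$min, rs$max))

fit <- linear_fit(paired$blood, paired$hair)
print(fit)
jsonlite::write_json(list(ratio = rs, fit = unclass(fit)),
                     "results/biomarker_summary.json", auto_unbox = TRUE, digits = NA)

# descriptive group splits (no hypothesis testing: per-subject study data
# would be needed for that to be meaningful)
sm <- timepoint_summary(bm, "blood", "T1", group_by = "smoker")
message("baseline blood by smoking status:")
print(sm, digits = 3, row.names = FALSE)
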