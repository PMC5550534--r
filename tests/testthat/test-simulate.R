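test_that("generator config validates its fields and names offenders", {
  expect_s3_class(generator_config(seed = 1), "hg_generator_config")
  err <- tryCatch(generator_config(seed = 1, bmi_sd = -1, smoker_prev = 2),
                  error = conditionMessage)
  expect_match(err, "bmi_sd")
  expect_match(err, "smoker_prev")
})

test_that("the same seed reproduces an identical study; components are independent", {
  a <- simulate_study(generator_config(seed = 11, n_subjects = 15))
  b <- simulate_study(generator_config(seed = 11, n_subjects = 15))
  expect_identical(a, b)
  d <- simulate_study(generator_config(seed = 12, n_subjects = 15))
  expect_false(identical(a$cohort$bmi, d$cohort$bmi))
  # per-component substreams: the cohort draw does not depend on whether the
  # fish samples were generated before or after it
  cfg <- generator_config(seed = 11, n_subjects = 15)
  invisible(generate_fish_samples(cfg))
  expect_identical(generate_cohort(cfg), a$cohort)
})

test_that("degenerate cohort: zero spread pins body weight to BMI x height^2", {
  cfg <- generator_config(seed = 1, n_subjects = 1, bmi_sd = 0, height_sd = 0)
  cohort <- generate_cohort(cfg)
  expect_equal(cohort$body_weight_kg, 26.9 * 1.77^2)
})

test_that("cohort anthropometry recovers its generating moments at large n", {
  n <- 10000
  cohort <- generate_cohort(generator_config(seed = 101, n_subjects = n))
  expect_true(all(cohort$bmi >= 17.8 & cohort$bmi <= 40.2))
  # 3 SE with the untruncated SD as a conservative bound
  expect_lt(abs(mean(cohort$bmi) - 26.9), 3 * 4.3 / sqrt(n))
  expect_lt(abs(stats::sd(cohort$bmi) / 4.3 - 1), 0.10)
  expect_lt(abs(mean(cohort$height_m) - 1.77), 3 * 0.07 / sqrt(n))
  expect_lt(abs(mean(cohort$smoker) - 0.21), 3 * sqrt(0.21 * 0.79 / n))
  expect_true(all(cohort$body_weight_kg > 0))
  expect_true(all(cohort$amalgam_fillings %in% 0:5))
})

test_that("fish samples honour their target distributions and bounds", {
  cfg <- generator_config(seed = 31)
  fs <- generate_fish_samples(cfg)
  expect_equal(nrow(fs), 8 * 12)
  expect_true(all(fs$conc_mg_per_kg >= 0))
  expect_true(all(fs$portion_mass_kg > 0))
  ref <- fish_reference()
  for (i in seq_len(nrow(ref))) {
    grp <- fs[fs$species_id == ref$species_id[i] & fs$state == ref$state[i], ]
    expect_true(all(grp$conc_mg_per_kg >= ref$min[i] & grp$conc_mg_per_kg <= ref$max[i]))
  }
  # moment recovery at large per-group n
  cfg_big <- generator_config(seed = 31, n_samples_per_species = 5000)
  fs_big <- generate_fish_samples(cfg_big)
  hoki <- fs_big[fs_big$species_id == "M_magellanicus" & fs_big$state == "fried", ]
  expect_lt(abs(mean(hoki$conc_mg_per_kg) - 0.109), 3 * 0.015 / sqrt(5000))
  expect_lt(abs(stats::sd(hoki$conc_mg_per_kg) / 0.015 - 1), 0.10)
  # degenerate: zero spread collapses to the mean
  sp0 <- fish_reference()
  sp0$sd <- 0
  fs0 <- generate_fish_samples(generator_config(seed = 1, species_params = sp0))
  expect_equal(unique(fs0$conc_mg_per_kg[fs0$species_id == "G_morhua" &
                                           fs0$state == "fried"]), 0.060)
  sp_bad <- fish_reference()
  sp_bad$min[1] <- sp_bad$max[1] + 1
  expect_error(generate_fish_samples(generator_config(seed = 1, species_params = sp_bad)),
               "infeasible")
})

test_that("the intervention schedule template matches the study design", {
  sched <- generate_meal_schedule()
  expect_equal(nrow(sched$events), 10)
  expect_equal(sched$consumption_days, 10)
  expect_equal(sched$n_weeks, 2L)
  expect_equal(sum(sched$events$mass_kg), 1.595) # "approximately 1.6 kg"
  counts <- table(sched$events$species_id)
  expect_equal(as.integer(counts[c("M_magellanicus", "G_chalcogrammus",
                                   "G_morhua", "P_virens")]),
               c(3L, 2L, 3L, 2L))
  expect_true(all(sched$events$state == "fried"))
  expect_true(all(sched$events$day[sched$events$species_id == "M_magellanicus"] %in% 1:3))
  expect_true(all(sched$events$day[sched$events$species_id == "P_virens"] %in% 11:12))
  expect_error(generate_meal_schedule("other_study"), "unknown")
})

test_that("biomarker trajectories calibrate to their population targets", {
  cfg <- generator_config(seed = 67)
  cohort <- generate_cohort(cfg)
  sched <- generate_meal_schedule()
  bm <- generate_biomarkers(cohort, sched, cfg)
  expect_true(all(bm$value >= 0))
  expect_true(all(bm$timepoint[bm$matrix == "hair"] %in% c("T1", "T4")))
  n <- nrow(cohort)
  t3 <- timepoint_summary(bm, "blood", "T3")
  expect_lt(abs(t3$mean - 1.28), 3 * 0.49 / sqrt(n))
  t1 <- timepoint_summary(bm, "blood", "T1")
  expect_lt(abs(t1$mean - 0.62), 3 * 0.41 / sqrt(n))
  # the biomarker stage closes the loop on the generating ratio
  rs <- ratio_summary(pair_hair_blood(bm))
  expect_lt(abs(rs$mean - 0.23), 3 * 0.23 * 0.3 / sqrt(n))
})

test_that("without exposure or noise, blood stays at baseline", {
  cfg <- generator_config(seed = 5, n_subjects = 8, uptake_cv = 0, ratio_cv = 0)
  cohort <- generate_cohort(cfg)
  none <- meal_schedule(data.frame(day = 1, species_id = "G_morhua",
                                   state = "fried", mass_kg = 0), n_weeks = 2)
  bm <- generate_biomarkers(cohort, none, cfg)
  blood <- bm[bm$matrix == "blood", ]
  base <- blood$value[blood$timepoint == "T1"]
  for (tp in c("T2", "T3", "T4")) {
    expect_equal(blood$value[blood$timepoint == tp], base)
  }
})

test_that("generated fixtures run end to end and reproduce the canonical total", {
  study <- simulate_study(generator_config(seed = 2))
  rep <- run_pipeline(study$fish_samples, study$schedule, study$cohort,
                      biomarkers = study$biomarkers)
  expect_true(all(is.finite(rep$exposure$results$ewi_ug_per_kg_week)))
  expect_true(all(c("fish_summary", "exposure", "biomarker") %in% names(rep)))
  # total from sampled concentrations stays within concentration sampling
  # error of the fixture-mean total: the dominant term is 3 hoki portions,
  # give 3 SE of the largest-variance species sums
  total <- rep$exposure$results$total_intake_ug[1]
  se_total <- 1000 * sqrt((3 * 0.150 * 0.015 / sqrt(12))^2 +
                            (2 * 0.147 * 0.009 / sqrt(12))^2 +
                            (3 * 0.173 * 0.009 / sqrt(12))^2 +
                            (2 * 0.166 * 0.019 / sqrt(12))^2)
  expect_lt(abs(total - 105.212), 4 * se_total)
})
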