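test_that("meal intake converts concentration times mass to micrograms", {
  expect_equal(meal_intake(0.109, 0.150), 16.35)
  expect_equal(meal_intake(0, 0.5), 0)
  expect_equal(meal_intake(0.055, 0.166), 9.13)
  expect_error(meal_intake(-0.1, 0.1), ">= 0")
  expect_error(meal_intake(0.1, -0.1), ">= 0")
})

test_that("the intervention schedule yields the canonical worked example", {
  sched <- generate_meal_schedule()
  total <- schedule_total_intake(sched, fried_conc())
  expect_equal(total, 105.212, tolerance = 1e-10)
  expect_equal(round(total), 105)
  expect_equal(daily_intake(total, sched), 10.5212, tolerance = 1e-10)
  expect_equal(round(daily_intake(total, sched), 1), 10.5)
  expect_equal(weekly_intake(total, sched), 52.606, tolerance = 1e-10)
  # calendar-day alternative divides by 14
  expect_equal(daily_intake(total, sched, per = "calendar"), total / 14)
})

test_that("schedule totals conserve per-meal intakes and degenerate cases", {
  empty <- meal_schedule(data.frame(day = integer(0), species_id = character(0),
                                    state = character(0), mass_kg = numeric(0)),
                         n_weeks = 1)
  expect_equal(schedule_total_intake(empty, fried_conc()), 0)
  one <- meal_schedule(data.frame(day = 1, species_id = "G_morhua",
                                  state = "fried", mass_kg = 0.173), 1)
  expect_equal(schedule_total_intake(one, fried_conc()),
               meal_intake(0.060, 0.173))
  expect_equal(daily_intake(schedule_total_intake(one, fried_conc()), one),
               schedule_total_intake(one, fried_conc()))
  set.seed(77)
  for (i in 1:10) {
    sched <- random_schedule()
    conc <- fried_conc()
    by_hand <- sum(vapply(seq_len(nrow(sched$events)), function(j) {
      ev <- sched$events[j, ]
      conc$conc_mg_per_kg[conc$species_id == ev$species_id] * ev$mass_kg * 1000
    }, numeric(1)))
    expect_equal(schedule_total_intake(sched, conc), by_hand, tolerance = 1e-12)
  }
})

test_that("unknown species in a schedule is reported by name", {
  sched <- meal_schedule(data.frame(day = 1, species_id = "T_albacares",
                                    state = "fried", mass_kg = 0.1), 1)
  expect_error(schedule_total_intake(sched, fried_conc()), "T_albacares")
})

test_that("intake arithmetic is linear in portion mass", {
  set.seed(42)
  sched <- random_schedule()
  doubled <- meal_schedule(transform(sched$events, mass_kg = 2 * mass_kg),
                           sched$n_weeks)
  conc <- fried_conc()
  t1 <- schedule_total_intake(sched, conc)
  t2 <- schedule_total_intake(doubled, conc)
  expect_equal(t2, 2 * t1, tolerance = 1e-12)
  expect_equal(weekly_intake(t2, doubled), 2 * weekly_intake(t1, sched))
  expect_equal(ewi(weekly_intake(t2, doubled), 80),
               2 * ewi(weekly_intake(t1, sched), 80))
  expect_equal(hazard_index(2 * 0.62, 1.6), 2 * hazard_index(0.62, 1.6))
})

test_that("body-weight normalisation round-trips and matches quoted rates", {
  expect_equal(ewi(112, 70), 1.6)
  expect_equal(ewi(0, 70), 0)
  expect_equal(ewi(52.606, 85), 0.6189, tolerance = 1e-4)
  set.seed(9)
  for (i in 1:20) {
    w <- stats::runif(1, 1, 200); bw <- stats::runif(1, 40, 150)
    expect_equal(ewi(w, bw) * bw, w, tolerance = 1e-12)
  }
  expect_error(ewi(50, 0), "> 0")
  expect_error(edi(10, -5), "> 0")
})

test_that("risk metrics: hazard index, percent of PTWI, mass equivalents", {
  expect_equal(round(hazard_index(0.62, 1.6), 2), 0.39)
  expect_equal(round(percent_ptwi(1.34, 1.6)), 84)
  expect_equal(percent_ptwi(1.6, 1.6), 100)
  expect_equal(hazard_index(1.6, 1.6), 1)
  set.seed(13)
  e <- stats::runif(50, 0, 3)
  expect_equal(percent_ptwi(e, 1.6), 100 * hazard_index(e, 1.6))
  expect_error(hazard_index(0.5, 0), "> 0")

  expect_equal(weekly_mass_equivalent(1.6, 70), 0.112)
  expect_equal(round(weekly_mass_equivalent(0.62, 70), 2), 0.04)
  expect_equal(weekly_mass_equivalent(0, 70), 0)
})

test_that("MeHg fraction scaling is bounded and linear", {
  expect_equal(mehg_from_thg(100), 100)
  expect_equal(mehg_from_thg(100, 0.9), 90)
  expect_equal(mehg_from_thg(3 + 4, 0.7), mehg_from_thg(3, 0.7) + mehg_from_thg(4, 0.7))
  expect_error(mehg_from_thg(1, 0), "fraction")
  expect_error(mehg_from_thg(1, 1.2), "fraction")
})

test_that("cohort exposure matches a per-subject loop oracle", {
  sched <- generate_meal_schedule()
  conc <- fried_conc()
  cohort <- generate_cohort(generator_config(seed = 21, n_subjects = 25))
  ce <- cohort_exposure(cohort, sched, conc)
  expect_equal(nrow(ce$results), 25)
  total <- schedule_total_intake(sched, conc)
  for (i in seq_len(nrow(cohort))) {
    bw <- cohort$body_weight_kg[i]
    expect_equal(ce$results$ewi_ug_per_kg_week[i], (total / 2) / bw, tolerance = 1e-12)
    expect_equal(ce$results$edi_ug_per_kg_day[i], (total / 10) / bw, tolerance = 1e-12)
  }
  expect_equal(ce$summary$ewi$mean, mean(ce$results$ewi_ug_per_kg_week))
  expect_equal(ce$summary$ewi$p95,
               percentile_oracle(ce$results$ewi_ug_per_kg_week, 0.95),
               tolerance = 1e-12)
  expect_equal(ce$results$pct_ptwi, 100 * ce$results$hazard_index)
  expect_equal(ce$results$exceeds_nrc, ce$results$ewi_ug_per_kg_week > 0.7)
})

test_that("a uniform cohort collapses to a single exposure value", {
  cohort <- data.frame(subject_id = paste0("U", 1:5), body_weight_kg = 80)
  ce <- cohort_exposure(cohort, generate_meal_schedule(), fried_conc())
  expect_equal(length(unique(ce$results$ewi_ug_per_kg_week)), 1)
  expect_equal(ce$summary$ewi$mean, ce$results$ewi_ug_per_kg_week[1])
})

test_that("the reported EWI extremes back out the implied body-weight range", {
  cohort <- data.frame(subject_id = c("light", "heavy"),
                       body_weight_kg = c(54.8, 146.1))
  ce <- cohort_exposure(cohort, generate_meal_schedule(), fried_conc())
  expect_equal(round(ce$results$ewi_ug_per_kg_week, 2), c(0.96, 0.36))
})

test_that("exceedance fraction is monotone, bounded, and respects the boundary rule", {
  e <- c(0.3, 0.5, 0.7, 0.9, 1.1)
  expect_equal(exceedance_fraction(e, 0), 1)
  expect_equal(exceedance_fraction(e, 2), 0)
  expect_equal(exceedance_fraction(e, 0.7), 0.4)        # strict > by default
  expect_equal(exceedance_fraction(e, 0.7, strict = TRUE), 0.6)
  lims <- seq(0, 1.5, by = 0.1)
  fr <- vapply(lims, function(l) exceedance_fraction(e, l), numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_true(all(fr >= 0 & fr <= 1))
  expect_error(exceedance_fraction(numeric(0), 0.5), "no exposure")
})

test_that("body weight resolves from BMI and height when absent", {
  cohort <- data.frame(subject_id = c("a", "b"),
                       body_weight_kg = c(70, NA),
                       bmi = c(30, 26.9), height_m = c(1.9, 1.77))
  out <- resolve_body_weight(cohort)
  expect_equal(out$body_weight_kg, c(70, 26.9 * 1.77^2))
  bad <- data.frame(subject_id = "z", body_weight_kg = NA, bmi = NA, height_m = NA)
  expect_error(resolve_body_weight(bad), "z")
})
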