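#' Construct a meal schedule
#'
#' A meal schedule is the ordered list of fish meals eaten over a
#' multi-week intervention: which species, in which preparation state, what
#' portion mass, on which (1-based) day. Consumption days are the distinct
#' days with at least one meal; weekends without fish do not count.
#'
#' @param events data.frame with columns `day`, `species_id`, `state`,
#'   `mass_kg`.
#' @param n_weeks number of calendar weeks the schedule spans (>= 1).
#' @return An object of class `meal_schedule`: list with `events` (sorted by
#'   day), `n_weeks` and `consumption_days`.
#' @export
#' @examples
#' meal_schedule(data.frame(day = 1:2, species_id = "G_morhua",
#'                          state = "fried", mass_kg = 0.173), n_weeks = 1)
meal_schedule <- function(events, n_weeks) {
  check_columns(events, c("day", "species_id", "state", "mass_kg"), "meals")
  if (!is.numeric(n_weeks) || n_weeks < 1 || n_weeks != round(n_weeks)) {
    stop("n_weeks must be a positive integer")
  }
  if (nrow(events) > 0) {
    if (any(events$day < 1 | events$day != round(events$day))) {
      stop("day must be a positive integer index")
    }
    if (any(events$mass_kg < 0)) stop("mass_kg must be >= 0")
    check_state(events$state)
    events <- events[order(events$day), , drop = FALSE]
    rownames(events) <- NULL
  }
  consumption_days <- length(unique(events$day))
  if (consumption_days > 7 * n_weeks) {
    stop("more consumption days than calendar days in ", n_weeks, " week(s)")
  }
  structure(
    list(events = events, n_weeks = as.integer(n_weeks),
         consumption_days = consumption_days),
    class = "meal_schedule"
  )
}

#' @export
print.meal_schedule <- function(x, ...) {
  cat(sprintf("meal schedule: %d meals on %d consumption days over %d week(s)\n",
              nrow(x$events), x$consumption_days, x$n_weeks))
  cat(sprintf("total fish mass: %.3f kg\n", sum(x$events$mass_kg)))
  invisible(x)
}

#' Mercury intake from a single meal
#'
#' Intake is concentration times portion mass; the factor 1000 converts the
#' mg/kg concentration basis to micrograms.
#'
#' @param conc THg concentration in the eaten fish, mg/kg wet weight.
#' @param mass portion mass, kg.
#' @return intake in micrograms (vectorised).
#' @export
#' @examples
#' meal_intake(0.109, 0.150) # one hoki portion: 16.35 ug
meal_intake <- function(conc, mass) {
  if (any(conc < 0)) stop("concentration must be >= 0")
  if (any(mass < 0)) stop("mass must be >= 0")
  conc * mass * 1000
}

#' Extract a species/state concentration lookup from fish summaries
#'
#' @param summaries data.frame from [summarize_fish()] (or [fish_reference()]);
#'   needs `species_id`, `state` and `mean`.
#' @return data.frame `species_id`, `state`, `conc_mg_per_kg` (the group mean).
#' @export
conc_table <- function(summaries) {
  check_columns(summaries, c("species_id", "state", "mean"), "summaries")
  data.frame(species_id = summaries$species_id, state = summaries$state,
             conc_mg_per_kg = summaries$mean)
}

lookup_conc <- function(events, conc) {
  check_columns(conc, c("species_id", "state", "conc_mg_per_kg"), "conc lookup")
  key <- paste(events$species_id, events$state)
  idx <- match(key, paste(conc$species_id, conc$state))
  if (anyNA(idx)) {
    missing <- unique(key[is.na(idx)])
    stop("no concentration for species/state: ", paste(missing, collapse = ", "))
  }
  conc$conc_mg_per_kg[idx]
}

#' Total mercury intake over a meal schedule
#'
#' Sums [meal_intake()] over every meal, resolving each meal's concentration
#' from a species/state lookup table.
#'
#' @param schedule a [meal_schedule()].
#' @param conc concentration lookup: data.frame with `species_id`, `state`,
#'   `conc_mg_per_kg` (see [conc_table()]).
#' @return total intake over the schedule, micrograms.
#' @export
schedule_total_intake <- function(schedule, conc) {
  stopifnot(inherits(schedule, "meal_schedule"))
  if (nrow(schedule$events) == 0) return(0)
  sum(meal_intake(lookup_conc(schedule$events, conc), schedule$events$mass_kg))
}

#' Average daily mercury intake
#'
#' Divides the schedule total by the number of fish-consumption days by
#' default — the convention under which a 105 ug total over 10 eating days
#' is a 10.5 ug/day intake — or by calendar days when `per = "calendar"`.
#'
#' @param total total intake, micrograms.
#' @param schedule a [meal_schedule()].
#' @param per `"consumption"` (default) or `"calendar"`.
#' @return intake in micrograms per day.
#' @export
daily_intake <- function(total, schedule, per = c("consumption", "calendar")) {
  per <- match.arg(per)
  if (total < 0) stop("total must be >= 0")
  days <- if (per == "consumption") schedule$consumption_days else 7 * schedule$n_weeks
  if (days < 1) stop("schedule has no consumption days")
  total / days
}

#' Average weekly mercury intake
#'
#' @param total total intake, micrograms.
#' @param schedule a [meal_schedule()].
#' @return intake in micrograms per week (`total / n_weeks`).
#' @export
weekly_intake <- function(total, schedule) {
  if (total < 0) stop("total must be >= 0")
  total / schedule$n_weeks
}

#' Body-weight-normalised intake rates
#'
#' The estimated weekly intake (EWI, ug/kg bw/week) and estimated daily
#' intake (EDI, ug/kg bw/day) divide the corresponding intake by body
#' weight. Note `ewi = 7 * edi` only holds when fish is eaten every calendar
#' day; the two are computed independently here.
#'
#' @param weekly weekly intake, ug/week.
#' @param daily daily intake, ug/day.
#' @param body_weight body weight, kg; must be > 0.
#' @return intake rate per kg body weight (vectorised over `body_weight`).
#' @export
#' @examples
#' ewi(112, 70) # the JECFA PTWI expressed for a 70 kg person: 1.6
ewi <- function(weekly, body_weight) {
  if (any(body_weight <= 0)) stop("body weight must be > 0")
  if (any(weekly < 0)) stop("weekly intake must be >= 0")
  weekly / body_weight
}

#' @rdname ewi
#' @export
edi <- function(daily, body_weight) {
  if (any(body_weight <= 0)) stop("body weight must be > 0")
  if (any(daily < 0)) stop("daily intake must be >= 0")
  daily / body_weight
}

#' Risk characterisation against a tolerable weekly intake
#'
#' The hazard index (HI) is the ratio of the estimated weekly intake to the
#' PTWI; the risk index expresses the same quantity as a percentage of the
#' PTWI. Values at or above 1 (100%) indicate the guideline is exceeded.
#'
#' @param ewi_value estimated weekly intake, ug/kg bw/week.
#' @param ptwi tolerable weekly intake, ug/kg bw/week; must be > 0.
#' @return `hazard_index()` returns the dimensionless ratio;
#'   `percent_ptwi()` the same times 100.
#' @export
#' @examples
#' hazard_index(0.62, 1.6) # 0.3875
#' percent_ptwi(1.34, 1.6) # 83.75
hazard_index <- function(ewi_value, ptwi) {
  if (any(ptwi <= 0)) stop("ptwi must be > 0")
  if (any(ewi_value < 0)) stop("ewi must be >= 0")
  ewi_value / ptwi
}

#' @rdname hazard_index
#' @export
percent_ptwi <- function(ewi_value, ptwi) {
  100 * hazard_index(ewi_value, ptwi)
}

#' Weekly mercury mass equivalent of an intake rate
#'
#' Converts a per-kg weekly intake rate into the absolute mercury mass per
#' week for a person of given body weight (the form in which PTWIs are often
#' quoted, e.g. 1.6 ug/kg bw/week is 0.112 mg/week at 70 kg).
#'
#' @param rate intake rate, ug/kg bw/week.
#' @param body_weight body weight, kg.
#' @return mercury mass, mg/week.
#' @export
weekly_mass_equivalent <- function(rate, body_weight) {
  if (any(rate < 0)) stop("rate must be >= 0")
  if (any(body_weight <= 0)) stop("body weight must be > 0")
  rate * body_weight / 1000
}

#' Methylmercury fraction of a total-mercury quantity
#'
#' Fish-muscle THg is predominantly (commonly assumed ~90-100%)
#' methylmercury; this applies the assumed fraction to any THg
#' concentration or intake.
#'
#' @param thg a THg quantity (any units).
#' @param fraction MeHg fraction, in (0, 1].
#' @return `thg * fraction`, same units.
#' @export
mehg_from_thg <- function(thg, fraction = 1.0) {
  if (!is.numeric(fraction) || any(fraction <= 0) || any(fraction > 1)) {
    stop("fraction must be in (0, 1]")
  }
  thg * fraction
}

#' Resolve body weight for a cohort table
#'
#' Explicit `body_weight_kg` wins; where absent, weight is derived as
#' BMI x height^2.
#'
#' @param cohort data.frame with `subject_id` and either `body_weight_kg` or
#'   both `bmi` and `height_m`.
#' @return the cohort with a complete, positive `body_weight_kg` column.
#' @export
resolve_body_weight <- function(cohort) {
  check_columns(cohort, "subject_id", "cohort")
  bw <- if ("body_weight_kg" %in% names(cohort)) cohort$body_weight_kg else rep(NA_real_, nrow(cohort))
  need <- is.na(bw)
  if (any(need)) {
    if (!all(c("bmi", "height_m") %in% names(cohort))) {
      stop("cohort: body_weight_kg absent for subject(s) ",
           paste(cohort$subject_id[need], collapse = ", "),
           " and no bmi/height_m columns to derive it")
    }
    bw[need] <- cohort$bmi[need] * cohort$height_m[need]^2
  }
  bad <- is.na(bw) | bw <= 0
  if (any(bad)) {
    stop("non-positive or missing body weight for subject(s): ",
         paste(cohort$subject_id[bad], collapse = ", "))
  }
  cohort$body_weight_kg <- bw
  cohort
}

#' Per-subject exposure and risk characterisation for a cohort
#'
#' Runs the full intake arithmetic for every subject: total intake over the
#' schedule, daily and weekly intake, EDI/EWI, percent of PTWI, hazard
#' index, and exceedance flags against the PTWI and the US-NRC weekly
#' limit. The PTWI comparison is made on the MeHg intake, i.e. the THg
#' intake scaled by `thresholds$mehg_fraction` (1.0 by default).
#'
#' @param cohort data.frame accepted by [resolve_body_weight()].
#' @param schedule a [meal_schedule()].
#' @param conc concentration lookup (see [conc_table()]).
#' @param thresholds a [default_thresholds()] set.
#' @param strict_exceedance if `TRUE`, subjects exactly at a limit are
#'   counted as exceeding; default `FALSE` (strict `>`, conservative toward
#'   compliance).
#' @return list with `results` (one row per subject: intakes, rates, risk
#'   metrics, flags), `summary` (mean/median/p95/min/max of EWI and
#'   percent-of-PTWI) and `exceedance` (fractions over the PTWI and NRC
#'   limits).
#' @export
cohort_exposure <- function(cohort, schedule, conc,
                            thresholds = default_thresholds(),
                            strict_exceedance = FALSE) {
  if (is.null(cohort) || nrow(cohort) == 0) stop("cohort is empty")
  stopifnot(inherits(thresholds, "threshold_set"))
  cohort <- resolve_body_weight(cohort)
  total <- schedule_total_intake(schedule, conc)
  daily <- daily_intake(total, schedule)
  weekly <- weekly_intake(total, schedule)
  bw <- cohort$body_weight_kg
  ewi_v <- ewi(weekly, bw)
  mehg_ewi <- mehg_from_thg(ewi_v, thresholds$mehg_fraction)
  hi <- hazard_index(mehg_ewi, thresholds$ptwi_mehg)
  over <- if (strict_exceedance) `>=` else `>`
  results <- data.frame(
    subject_id = cohort$subject_id,
    body_weight_kg = bw,
    total_intake_ug = total,
    daily_intake_ug = daily,
    weekly_intake_ug = weekly,
    edi_ug_per_kg_day = edi(daily, bw),
    ewi_ug_per_kg_week = ewi_v,
    pct_ptwi = 100 * hi,
    hazard_index = hi,
    exceeds_ptwi = over(mehg_ewi, thresholds$ptwi_mehg),
    exceeds_nrc = over(mehg_ewi, thresholds$nrc_limit)
  )
  list(
    results = results,
    summary = list(ewi = dist_summary(results$ewi_ug_per_kg_week),
                   pct_ptwi = dist_summary(results$pct_ptwi)),
    exceedance = list(ptwi = mean(results$exceeds_ptwi),
                      nrc = mean(results$exceeds_nrc))
  )
}

#' Fraction of subjects exceeding an intake limit
#'
#' @param results the `results` data.frame from [cohort_exposure()], or a
#'   numeric vector of EWI values (ug/kg bw/week).
#' @param limit weekly intake limit, ug/kg bw/week.
#' @param strict count subjects exactly at the limit as exceeding
#'   (default `FALSE`: exceedance means strictly above the limit).
#' @return proportion in `[0, 1]`.
#' @export
exceedance_fraction <- function(results, limit, strict = FALSE) {
  x <- if (is.data.frame(results)) results$ewi_ug_per_kg_week else results
  if (length(x) == 0) stop("no exposure results")
  if (limit < 0) stop("limit must be >= 0")
  if (strict) mean(x >= limit) else mean(x > limit)
}
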