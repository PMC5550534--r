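#' Weekly intake rate for a reference consumer
#'
#' Projects the EWI of a hypothetical person eating the same portion of one
#' species a fixed number of times per week, e.g. a 70 kg person eating a
#' 150 g hoki portion three times a week.
#'
#' @param conc THg concentration of the eaten fish, mg/kg wet weight.
#' @param portion_mass portion mass, kg.
#' @param meals_per_week number of such meals per week (>= 0).
#' @param body_weight body weight, kg.
#' @return EWI in ug/kg bw/week.
#' @export
#' @examples
#' reference_person_weekly(0.109, 0.150, 3, 70) # ~0.70
reference_person_weekly <- function(conc, portion_mass, meals_per_week, body_weight) {
  if (meals_per_week < 0 || meals_per_week != round(meals_per_week)) {
    stop("meals_per_week must be a non-negative integer")
  }
  if (body_weight <= 0) stop("body weight must be > 0")
  meals_per_week * meal_intake(conc, portion_mass) / body_weight
}

#' Weekly intake from eating a single species on consecutive days
#'
#' The "what if people ate only this fish" projection: one portion per day
#' for up to 7 days of one week.
#'
#' @param conc THg concentration, mg/kg wet weight.
#' @param portion_mass portion mass, kg.
#' @param days number of eating days in the week, 0 to 7.
#' @param body_weight body weight, kg.
#' @return EWI in ug/kg bw/week.
#' @export
#' @examples
#' single_species_week(0.109, 0.150, 7, 85.4) # ~1.34
single_species_week <- function(conc, portion_mass, days, body_weight) {
  if (days < 0 || days > 7 || days != round(days)) {
    stop("days must be an integer in [0, 7] for a weekly quantity")
  }
  if (body_weight <= 0) stop("body weight must be > 0")
  days * meal_intake(conc, portion_mass) / body_weight
}

#' Maximum fish mass consumable per week under an intake limit
#'
#' Inverts the intake arithmetic: the fish mass whose weekly intake exactly
#' meets a per-kg weekly limit for a person of given body weight.
#'
#' @param conc THg concentration of the fish, mg/kg wet weight; must be > 0.
#' @param limit weekly intake limit, ug/kg bw/week.
#' @param body_weight body weight, kg.
#' @return allowable fish mass, kg/week.
#' @export
#' @examples
#' max_allowable_weekly_mass(0.109, 1.6, 70) # ~1.03 kg of fried hoki
max_allowable_weekly_mass <- function(conc, limit, body_weight) {
  if (conc <= 0) stop("no finite bound: concentration must be > 0")
  if (limit < 0) stop("limit must be >= 0")
  if (body_weight <= 0) stop("body weight must be > 0")
  limit * body_weight / (conc * 1000)
}
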