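#' Reference mercury concentrations and portion masses for the study species
#'
#' Descriptive statistics of total mercury (THg, mg/kg wet weight) in the
#' muscle tissue of the four Gadiformes species used in the two-week
#' fish-meal intervention, in both raw and fried states, together with the
#' mean portion (fillet) masses. Twelve tissue samples were measured per
#' species and state. These values serve both as a fixture for the worked
#' examples and as calibration targets for the synthetic-data generator.
#'
#' @return A data.frame with one row per species/state: `species_id`,
#'   `common_name`, `academic_name`, `state`, `n`, `mean`, `sd`, `min`,
#'   `max`, `median`, `p95` (all concentrations in mg/kg wet weight) and
#'   `portion_mass_mean`, `portion_mass_sd` (kg).
#' @export
#' @examples
#' fried <- subset(fish_reference(), state == "fried")
#' fried[, c("species_id", "mean", "portion_mass_mean")]
fish_reference <- function() {
  df <- rbind(
    data.frame(
      species_id = c("M_magellanicus", "G_chalcogrammus", "G_morhua", "P_virens"),
      common_name = c("hoki (Patagonian grenadier)", "pollock", "cod", "coalfish (saithe)"),
      academic_name = c("Macruronus magellanicus", "Gadus chalcogrammus",
                        "Gadus morhua", "Pollachius virens"),
      state = "raw",
      n = 12L,
      mean = c(0.105, 0.018, 0.049, 0.041),
      sd = c(0.015, 0.006, 0.006, 0.005),
      min = c(0.075, 0.010, 0.041, 0.027),
      max = c(0.130, 0.028, 0.060, 0.046),
      median = c(0.11, 0.02, 0.05, 0.04),
      p95 = c(0.12, 0.03, 0.06, 0.05),
      portion_mass_mean = c(0.175, 0.166, 0.189, 0.189),
      portion_mass_sd = c(0.015, 0.020, 0.025, 0.023)
    ),
    data.frame(
      species_id = c("M_magellanicus", "G_chalcogrammus", "G_morhua", "P_virens"),
      common_name = c("hoki (Patagonian grenadier)", "pollock", "cod", "coalfish (saithe)"),
      academic_name = c("Macruronus magellanicus", "Gadus chalcogrammus",
                        "Gadus morhua", "Pollachius virens"),
      state = "fried",
      n = 12L,
      mean = c(0.109, 0.023, 0.060, 0.055),
      sd = c(0.015, 0.009, 0.009, 0.019),
      min = c(0.052, 0.009, 0.049, 0.035),
      max = c(0.139, 0.033, 0.072, 0.090),
      median = c(0.11, 0.02, 0.06, 0.05),
      p95 = c(0.13, 0.03, 0.07, 0.09),
      portion_mass_mean = c(0.150, 0.147, 0.173, 0.166),
      portion_mass_sd = c(0.014, 0.019, 0.026, 0.021)
    )
  )
  rownames(df) <- NULL
  df
}

#' Default regulatory thresholds for mercury risk characterisation
#'
#' The limit set used throughout the package:
#' \describe{
#'   \item{ptwi_mehg}{JECFA provisional tolerable weekly intake for
#'     methylmercury, 1.6 ug/kg bw/week.}
#'   \item{ptwi_thg}{PTWI for total mercury, 4 ug/kg bw/week.}
#'   \item{nrc_limit}{US National Research Council weekly intake limit,
#'     0.7 ug/kg bw/week (2.3-fold stricter than JECFA).}
#'   \item{mpc}{EC 1881/2006 maximum permitted concentration in most fish,
#'     0.5 mg/kg wet weight.}
#'   \item{ptwi_japan}{PTWI applied in Japan, 3.4 ug MeHg/kg bw/week.}
#'   \item{mehg_fraction}{assumed MeHg share of measured THg in fish muscle.
#'     Defaults to 1.0 because headline risk figures conventionally equate
#'     THg in fish with MeHg; 0.9 is the common literature alternative.}
#' }
#'
#' @param ... named overrides of the defaults listed above.
#' @return A named list of class `threshold_set`.
#' @export
#' @examples
#' default_thresholds(mehg_fraction = 0.9)
default_thresholds <- function(...) {
  ts <- list(
    ptwi_mehg = 1.6, ptwi_thg = 4.0, nrc_limit = 0.7,
    mpc = 0.5, ptwi_japan = 3.4, mehg_fraction = 1.0
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(ts))
  if (length(unknown) > 0) {
    stop("unknown threshold field(s): ", paste(unknown, collapse = ", "))
  }
  ts[names(over)] <- over
  for (nm in setdiff(names(ts), "mehg_fraction")) {
    if (!is.numeric(ts[[nm]]) || ts[[nm]] <= 0) {
      stop("threshold '", nm, "' must be a positive number")
    }
  }
  f <- ts$mehg_fraction
  if (!is.numeric(f) || f <= 0 || f > 1) {
    stop("mehg_fraction must be in (0, 1]")
  }
  class(ts) <- "threshold_set"
  ts
}

#' Published weekly mercury intake estimates for context
#'
#' A static table of estimated weekly Hg/MeHg intakes reported for other
#' populations, shipped for comparison only: the underlying consumption and
#' concentration data are not available, so none of these values are
#' recomputed by this package.
#'
#' @return A data.frame with columns `location`, `population`,
#'   `ewi_ug_per_kg_bw_week` and `note`.
#' @export
literature_intakes <- function() {
  data.frame(
    location = c("Netherlands", "France", "France", "Portugal", "Catalonia (Spain)",
                 "Italy", "Hong Kong", "Hong Kong", "Japan", "Nepal (Lake Phewa)",
                 "Nepal (Lake Phewa)"),
    population = c("adults (SCOOP)", "adults (SCOOP)", "adults >14 y",
                   "adults (SCOOP)", "general population", "median consumers",
                   "students, average consumer (MeHg, median)",
                   "students, high consumer (MeHg, median)",
                   "intervention volunteers (national PTWI 3.4)",
                   "visitors (minimum)", "hotel owners (maximum)"),
    ewi_ug_per_kg_bw_week = c(0.1, 0.3, 0.43, 1.6, 0.78, NA, 0.45, 1.3, NA,
                              0.05, 3.71),
    note = c("upper bound <0.1", "SCOOP report", "mean; median 0.30, p97.5 1.78",
             "SCOOP report", "compared against PTWI THg 5",
             "0.88 ug/week for 65 kg person (55% of PTWI)",
             "midpoint of reported 0.4-0.5", "midpoint of reported 1.2-1.4",
             "baseline hair THg 2.30 +/- 1.08 ug/g",
             "fish consumption 0.1 kg/week", "fish consumption 7.5 kg/week")
  )
}
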