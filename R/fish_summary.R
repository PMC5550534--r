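#' Summarize tissue mercury measurements for one species and state
#'
#' Computes the descriptive statistics reported for fish tissue THg:
#' arithmetic mean, sample (n-1) standard deviation, median, 95th
#' percentile, and range, plus portion-mass statistics when portion masses
#' are available. The 95th percentile uses linear interpolation between
#' closest ranks (quantile type 7).
#'
#' @param samples data.frame of measurements for a single species/state with
#'   columns `species_id`, `state` and `conc_mg_per_kg`; an optional
#'   `portion_mass_kg` column is summarised too.
#' @param portion_masses optional numeric vector of portion masses (kg);
#'   overrides the `portion_mass_kg` column.
#' @return One-row data.frame: `species_id`, `state`, `n`, `mean`, `sd`,
#'   `median`, `p95`, `min`, `max`, `portion_mass_mean`, `portion_mass_sd`.
#' @export
#' @examples
#' s <- data.frame(species_id = "G_morhua", state = "fried",
#'                 conc_mg_per_kg = c(0.049, 0.060, 0.072))
#' summarize_samples(s)
summarize_samples <- function(samples, portion_masses = NULL) {
  if (is.null(samples) || nrow(samples) == 0) stop("no samples")
  check_columns(samples, c("species_id", "state", "conc_mg_per_kg"), "samples")
  if (length(unique(samples$species_id)) > 1 || length(unique(samples$state)) > 1) {
    stop("heterogeneous group: samples mix species or states")
  }
  check_state(samples$state)
  x <- samples$conc_mg_per_kg
  if (any(!is.finite(x)) || any(x < 0)) stop("concentrations must be finite and >= 0")
  if (is.null(portion_masses) && "portion_mass_kg" %in% names(samples)) {
    portion_masses <- samples$portion_mass_kg
  }
  pm_mean <- if (is.null(portion_masses)) NA_real_ else mean(portion_masses)
  pm_sd <- if (is.null(portion_masses) || length(portion_masses) < 2) NA_real_ else stats::sd(portion_masses)
  data.frame(
    species_id = samples$species_id[1],
    state = samples$state[1],
    n = length(x),
    mean = mean(x),
    sd = if (length(x) > 1) stats::sd(x) else NA_real_,
    median = stats::median(x),
    p95 = p95(x),
    min = min(x),
    max = max(x),
    portion_mass_mean = pm_mean,
    portion_mass_sd = pm_sd
  )
}

#' Summarize a whole fish-sample table by species and state
#'
#' @param samples data.frame of measurements in the `fish_samples.csv` schema
#'   (`species_id`, `state`, `conc_mg_per_kg`, optionally `portion_mass_kg`).
#' @param mpc optional maximum permitted concentration (mg/kg); when given,
#'   `mpc_compliant` and `mpc_margin` columns are appended.
#' @return data.frame with one summary row per species/state group.
#' @export
summarize_fish <- function(samples, mpc = NULL) {
  check_columns(samples, c("species_id", "state", "conc_mg_per_kg"), "samples")
  groups <- split(samples, interaction(samples$species_id, samples$state, drop = TRUE))
  out <- do.call(rbind, lapply(groups, summarize_samples))
  out <- out[order(out$species_id, out$state), ]
  rownames(out) <- NULL
  if (!is.null(mpc)) {
    chk <- lapply(seq_len(nrow(out)), function(i) mpc_check(out[i, ], mpc))
    out$mpc_compliant <- vapply(chk, `[[`, logical(1), "compliant")
    out$mpc_margin <- vapply(chk, `[[`, numeric(1), "margin")
  }
  out
}

#' Compare mercury levels between raw and fried preparations
#'
#' Reports the signed difference in mean THg between the fried and raw
#' states of one species, in three readings: `abs_diff` (mg/kg),
#' `reported_pct` (the absolute mg/kg difference multiplied by 100 — the
#' idiosyncratic "percent" notation used in some intervention reports,
#' reproduced here under a clearly distinct name) and `rel_pct` (the
#' conventional relative change, 100 * abs_diff / raw mean).
#'
#' @param raw,fried one-row summaries from [summarize_samples()] for the
#'   same species in the raw and fried state respectively.
#' @return list with `species_id`, `abs_diff`, `reported_pct`, `rel_pct`.
#' @export
raw_fried_difference <- function(raw, fried) {
  if (raw$species_id != fried$species_id) {
    stop("species mismatch: ", raw$species_id, " vs ", fried$species_id)
  }
  if (raw$state != "raw" || fried$state != "fried") {
    stop("arguments must be a raw summary and a fried summary, in that order")
  }
  d <- fried$mean - raw$mean
  list(
    species_id = raw$species_id,
    abs_diff = d,
    reported_pct = d * 100,
    rel_pct = 100 * d / raw$mean
  )
}

#' Check a species summary against a maximum permitted concentration
#'
#' Compliance is assessed on the mean concentration (the usual reading of
#' "average concentration did not exceed the MPC"); `strict = TRUE` instead
#' compares the per-sample maximum. The boundary is inclusive: a mean equal
#' to the MPC is compliant.
#'
#' @param summary one-row summary from [summarize_samples()].
#' @param mpc maximum permitted concentration, mg/kg wet weight; must be > 0.
#' @param strict compare the group maximum instead of the mean.
#' @return list with `compliant` (logical) and `margin` (mpc minus the
#'   compared value, mg/kg; negative when non-compliant).
#' @export
mpc_check <- function(summary, mpc = 0.5, strict = FALSE) {
  if (!is.numeric(mpc) || mpc <= 0) stop("mpc must be > 0")
  value <- if (strict) summary$max else summary$mean
  list(compliant = value <= mpc, margin = mpc - value)
}

#' Detection and quantification limits from the blank standard deviation
#'
#' The instrument QC convention: the detection limit is 3 times, and the
#' quantification limit 6 times, the standard deviation of repeated blank
#' measurements.
#'
#' @param blank_sd standard deviation of the blank signal (ng); must be >= 0.
#' @return list with `detection_limit` and `quantification_limit` (ng).
#' @export
#' @examples
#' qc_limits(0.00085)
qc_limits <- function(blank_sd) {
  if (!is.numeric(blank_sd) || blank_sd < 0) stop("blank_sd must be >= 0")
  list(detection_limit = 3 * blank_sd, quantification_limit = 6 * blank_sd)
}

#' Certified reference material recovery
#'
#' @param measured measured concentration(s).
#' @param certified certified concentration(s); must be > 0.
#' @return recovery in percent, `100 * measured / certified` (vectorised).
#' @export
recovery <- function(measured, certified) {
  if (any(certified <= 0)) stop("certified concentration must be > 0")
  if (any(measured < 0)) stop("measured concentration must be >= 0")
  100 * measured / certified
}
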