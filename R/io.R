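# File interchange: comma-separated, UTF-8, "." decimal, mandatory header.
# Units are encoded in column names (_mg_per_kg, _kg, _ug_per_l) so files
# are self-describing.

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, ": file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, required, what)
  df
}

check_nonnegative <- function(df, col, what) {
  bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
  if (length(bad) > 0) {
    stop(sprintf("%s: negative %s at row %s", what, col,
                 paste(bad, collapse = ", ")))
  }
  invisible(df)
}

#' Read a fish-sample table
#'
#' Expects `fish_samples.csv` columns: `species_id`, `state`,
#' `conc_mg_per_kg`, optionally `academic_name`, `sample_index`,
#' `portion_mass_kg`.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_fish_samples <- function(path) {
  df <- read_csv_checked(path, c("species_id", "state", "conc_mg_per_kg"),
                         "fish_samples")
  check_state(df$state)
  check_nonnegative(df, "conc_mg_per_kg", "fish_samples")
  if ("portion_mass_kg" %in% names(df)) {
    check_nonnegative(df, "portion_mass_kg", "fish_samples")
  }
  df
}

#' Read a meal schedule
#'
#' Expects `meals.csv` columns: `day`, `species_id`, `state`, `mass_kg`.
#' The number of weeks is taken from the largest day index unless given.
#'
#' @param path CSV file path.
#' @param n_weeks optional week count; default `ceiling(max(day) / 7)`.
#' @return a [meal_schedule()].
#' @export
read_meals <- function(path, n_weeks = NULL) {
  df <- read_csv_checked(path, c("day", "species_id", "state", "mass_kg"), "meals")
  check_nonnegative(df, "mass_kg", "meals")
  if (nrow(df) == 0) stop("meals: no meal events in ", path)
  if (is.null(n_weeks)) n_weeks <- ceiling(max(df$day) / 7)
  meal_schedule(df, n_weeks = n_weeks)
}

#' Read a cohort table
#'
#' Expects `cohort.csv` columns: `subject_id` and `body_weight_kg` (may be
#' empty where `bmi` and `height_m` are present to derive it), optionally
#' `smoker`, `amalgam_fillings`.
#'
#' @param path CSV file path.
#' @return data.frame with resolved positive `body_weight_kg`.
#' @export
read_cohort <- function(path) {
  df <- read_csv_checked(path, "subject_id", "cohort")
  resolve_body_weight(df)
}

#' Read longitudinal biomarker records
#'
#' Expects `biomarkers.csv` columns: `subject_id`, `timepoint` (T1-T4),
#' `matrix` (`blood`/`hair`), `value`. Hair records are only valid at T1
#' and T4, matching the collection design.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_biomarkers <- function(path) {
  df <- read_csv_checked(path, c("subject_id", "timepoint", "matrix", "value"),
                         "biomarkers")
  bad_tp <- setdiff(unique(df$timepoint), c("T1", "T2", "T3", "T4"))
  if (length(bad_tp) > 0) stop("biomarkers: unknown timepoint ", paste(bad_tp, collapse = ", "))
  bad_mx <- setdiff(unique(df$matrix), c("blood", "hair"))
  if (length(bad_mx) > 0) stop("biomarkers: unknown matrix ", paste(bad_mx, collapse = ", "))
  check_nonnegative(df, "value", "biomarkers")
  hair_tp <- unique(df$timepoint[df$matrix == "hair"])
  if (length(setdiff(hair_tp, c("T1", "T4"))) > 0) {
    stop("biomarkers: hair records only exist at T1 and T4")
  }
  df
}

#' Write a table in the package's CSV dialect
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full exposure-assessment pipeline
#'
#' Chains the stages: fish summaries (with MPC compliance), cohort exposure
#' and risk characterisation, and — when biomarker records are supplied —
#' the biomarker stage (timepoint summaries, hair-to-blood ratio
#' distribution, hair-on-blood linear fit). Inputs may be file paths (read
#' through the validating readers) or in-memory objects. Any stage failure
#' aborts with the stage name and cause.
#'
#' @param fish_samples fish-sample table or path.
#' @param meals a [meal_schedule()] or path.
#' @param cohort cohort table or path.
#' @param biomarkers optional biomarker records or path.
#' @param thresholds a [default_thresholds()] set.
#' @param out_dir optional directory; when given, writes
#'   `species_summary.csv`, `exposure.csv` and `report.json` there.
#' @return list with `fish_summary`, `exposure` (see [cohort_exposure()])
#'   and optionally `biomarker`.
#' @export
run_pipeline <- function(fish_samples, meals, cohort, biomarkers = NULL,
                         thresholds = default_thresholds(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("%s stage failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  fish_samples <- stage("input", if (is.character(fish_samples)) read_fish_samples(fish_samples) else fish_samples)
  schedule <- stage("input", if (is.character(meals)) read_meals(meals) else meals)
  cohort <- stage("input", if (is.character(cohort)) read_cohort(cohort) else cohort)
  if (is.character(biomarkers)) biomarkers <- stage("input", read_biomarkers(biomarkers))

  fish_sum <- stage("summarize", summarize_fish(fish_samples, mpc = thresholds$mpc))
  expo <- stage("exposure", cohort_exposure(cohort, schedule, conc_table(fish_sum),
                                            thresholds = thresholds))
  report <- list(fish_summary = fish_sum, exposure = expo)

  if (!is.null(biomarkers)) {
    report$biomarker <- stage("biomarker", {
      tps <- expand.grid(timepoint = c("T1", "T2", "T3", "T4"),
                         matrix = c("blood", "hair"), stringsAsFactors = FALSE)
      tabs <- lapply(seq_len(nrow(tps)), function(i) {
        sel <- biomarkers[biomarkers$matrix == tps$matrix[i] &
                            biomarkers$timepoint == tps$timepoint[i], ]
        if (nrow(sel) == 0) return(NULL)
        cbind(matrix = tps$matrix[i], timepoint = tps$timepoint[i],
              timepoint_summary(biomarkers, tps$matrix[i], tps$timepoint[i]))
      })
      paired <- pair_hair_blood(biomarkers)
      list(timepoints = do.call(rbind, tabs[!vapply(tabs, is.null, logical(1))]),
           ratio = ratio_summary(paired),
           fit = linear_fit(paired$blood, paired$hair))
    })
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(fish_sum, file.path(out_dir, "species_summary.csv"))
    write_table(expo$results, file.path(out_dir, "exposure.csv"))
    json <- list(
      exposure_summary = expo$summary,
      exceedance = expo$exceedance,
      thresholds = unclass(thresholds)
    )
    if (!is.null(report$biomarker)) {
      json$biomarker <- list(ratio = report$biomarker$ratio,
                             fit = unclass(report$biomarker$fit))
    }
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}
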