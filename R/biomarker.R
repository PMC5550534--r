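#' Descriptive summary of biomarker records at one timepoint
#'
#' Longitudinal biomonitoring records hold blood THg (ug/l) at four
#' timepoints (T1 = first day, T2 = end of week 1, T3 = day 10, T4 = one
#' month after the study) and hair THg (ug/g) at T1 and T4. This summarises
#' one matrix at one timepoint, optionally split by a covariate such as
#' smoking status or amalgam fillings (descriptive only; no hypothesis
#' testing).
#'
#' @param records data.frame with columns `subject_id`, `timepoint`,
#'   `matrix`, `value`, plus any covariate columns used for grouping.
#' @param matrix `"blood"` or `"hair"`.
#' @param timepoint one of `"T1"`..`"T4"`.
#' @param group_by optional name of a covariate column in `records`.
#' @return data.frame with columns `group`, `n`, `mean`, `sd` (one row,
#'   group `"all"`, when `group_by` is `NULL`).
#' @export
timepoint_summary <- function(records, matrix, timepoint, group_by = NULL) {
  check_columns(records, c("subject_id", "timepoint", "matrix", "value"), "biomarkers")
  sel <- records[records$matrix == matrix & records$timepoint == timepoint, , drop = FALSE]
  if (nrow(sel) == 0) {
    stop("no matching records for ", matrix, " at ", timepoint)
  }
  if (is.null(group_by)) {
    g <- rep("all", nrow(sel))
  } else {
    check_columns(sel, group_by, "biomarkers")
    g <- as.character(sel[[group_by]])
  }
  out <- do.call(rbind, lapply(split(sel$value, g), function(v) {
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }))
  data.frame(group = rownames(out), out, row.names = NULL)
}

#' Hair-to-blood mercury ratio
#'
#' Computed in the matrices' native units — hair in ug/g over blood in ug/l —
#' matching the convention in which the cohort mean ratio is ~0.23. (The
#' textbook ~250:1 hair:blood ratio uses matched mass units, ug/kg over
#' ug/kg; the two differ by the unit factor of 1000 and blood density.)
#'
#' @param hair hair THg, ug/g.
#' @param blood blood THg, ug/l; must be > 0.
#' @return dimensionless ratio per the unit convention above (vectorised).
#' @export
#' @examples
#' hair_blood_ratio(0.29, 1.28) # ~0.227
hair_blood_ratio <- function(hair, blood) {
  if (any(blood <= 0)) stop("blood concentration must be > 0")
  if (any(hair < 0)) stop("hair concentration must be >= 0")
  hair / blood
}

#' Pair each subject's hair and blood values across timepoints
#'
#' Default pairing follows the study design: hair collected one month after
#' the intervention (T4) against blood collected at the end of exposure
#' (T3), the lag reflecting hair growth.
#'
#' @param records biomarker records (see [timepoint_summary()]).
#' @param hair_timepoint,blood_timepoint timepoints to pair.
#' @return data.frame `subject_id`, `blood`, `hair`, subjects with both
#'   measurements only.
#' @export
pair_hair_blood <- function(records, hair_timepoint = "T4", blood_timepoint = "T3") {
  check_columns(records, c("subject_id", "timepoint", "matrix", "value"), "biomarkers")
  hair <- records[records$matrix == "hair" & records$timepoint == hair_timepoint,
                  c("subject_id", "value")]
  blood <- records[records$matrix == "blood" & records$timepoint == blood_timepoint,
                   c("subject_id", "value")]
  names(hair)[2] <- "hair"
  names(blood)[2] <- "blood"
  out <- merge(blood, hair, by = "subject_id")
  if (nrow(out) == 0) stop("no subjects with paired hair and blood records")
  out[, c("subject_id", "blood", "hair")]
}

#' Distribution of per-subject hair-to-blood ratios
#'
#' Mean of per-subject ratios by default ("average ratio" read as a
#' per-subject distribution, consistent with reporting its median, 95th
#' percentile and range); `method = "ratio_of_means"` gives the pooled
#' alternative.
#'
#' @param paired data.frame from [pair_hair_blood()].
#' @param method `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @return list with `mean`, `median`, `p95`, `min`, `max` of the ratio
#'   (for `"ratio_of_means"`, only `mean` is meaningful and the rest are the
#'   same pooled value).
#' @export
ratio_summary <- function(paired, method = c("mean_of_ratios", "ratio_of_means")) {
  method <- match.arg(method)
  if (method == "mean_of_ratios") {
    dist_summary(hair_blood_ratio(paired$hair, paired$blood))
  } else {
    r <- mean(paired$hair) / mean(paired$blood)
    list(mean = r, median = r, p95 = r, min = r, max = r)
  }
}

#' Ordinary least-squares fit of hair on blood mercury
#'
#' @param x predictor values (blood THg, ug/l).
#' @param y response values (paired hair THg, ug/g).
#' @return list of class `hg_linear_fit`: `slope`, `intercept`, `r`
#'   (Pearson correlation) and `n`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 points")
  if (stats::var(x) == 0) stop("zero variance in predictor")
  fit <- stats::lm(y ~ x)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r = if (stats::var(y) == 0) 0 else stats::cor(x, y),
         n = length(x)),
    class = "hg_linear_fit"
  )
}

#' @export
print.hg_linear_fit <- function(x, ...) {
  cat(sprintf("linear fit (n = %d): hair = %.4f + %.4f * blood, r = %.3f\n",
              x$n, x$intercept, x$slope, x$r))
  invisible(x)
}
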