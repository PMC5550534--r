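# Independent oracles, deliberately coded from first principles and never
# calling the implementation they check.

# percentile by sort and linear interpolation between closest ranks
percentile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  if (n == 1) return(s[1])
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

# OLS slope/intercept/r from the normal equations, plain sums
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y)
  sxx <- sum(x^2); syy <- sum(y^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- sy / n - slope * sx / n
  denom <- sqrt(n * sxx - sx^2) * sqrt(n * syy - sy^2)
  r <- if (denom == 0) 0 else (n * sxy - sx * sy) / denom
  list(slope = slope, intercept = intercept, r = r)
}

# fried-state mean concentrations of the four study species
fried_conc <- function() {
  conc_table(fish_reference()[fish_reference()$state == "fried", ])
}

# a random but valid meal schedule for property tests
random_schedule <- function(n_events = 8, n_weeks = 2) {
  ids <- c("M_magellanicus", "G_chalcogrammus", "G_morhua", "P_virens")
  meal_schedule(
    data.frame(
      day = sample(seq_len(7 * n_weeks), n_events, replace = TRUE),
      species_id = sample(ids, n_events, replace = TRUE),
      state = "fried",
      mass_kg = round(stats::runif(n_events, 0.05, 0.3), 3)
    ),
    n_weeks = n_weeks
  )
}
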