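#' Truncate a number to a fixed number of decimals
#'
#' Truncation (toward zero) rather than rounding; some regulatory tables
#' print intake values this way.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return `x` truncated to `digits` decimals.
#' @export
#' @examples
#' trunc_to(16.35, 1) # 16.3
trunc_to <- function(x, digits = 0) {
  f <- 10^digits
  trunc(x * f) / f
}

# 95th percentile, linear interpolation between closest ranks (quantile type 7)
p95 <- function(x) stats::quantile(x, 0.95, type = 7, names = FALSE)

# five-number-plus-mean summary used for EWI / ratio distributions
dist_summary <- function(x) {
  list(
    mean = mean(x), median = stats::median(x), p95 = p95(x),
    min = min(x), max = max(x)
  )
}

# derive a per-component RNG seed from the single global seed so that adding
# a component never perturbs the draws of earlier ones
substream_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  (abs(as.double(seed)) * 7 + component * 104729) %% 2147483647
}

# truncated-normal draws by rejection; exact for sd = 0
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    if (mean < lower || mean > upper) stop("degenerate mean outside bounds")
    return(rep(mean, n))
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

# closed-form moments of a normal truncated to [a, b]
tnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  Z <- stats::pnorm(be) - stats::pnorm(al)
  da <- stats::dnorm(al); db <- stats::dnorm(be)
  ada <- if (is.finite(al)) al * da else 0
  bdb <- if (is.finite(be)) be * db else 0
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (ada - bdb) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)), mass = Z)
}

# closed-form moments of a lognormal truncated to [a, b]
tlnorm_moments <- function(mu, s, a, b) {
  la <- (log(max(a, 0)) - mu) / s
  lb <- (log(b) - mu) / s
  Z <- stats::pnorm(lb) - stats::pnorm(la)
  m1 <- exp(mu + s^2 / 2) * (stats::pnorm(lb - s) - stats::pnorm(la - s)) / Z
  m2 <- exp(2 * mu + 2 * s^2) * (stats::pnorm(lb - 2 * s) - stats::pnorm(la - 2 * s)) / Z
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)), mass = Z)
}

# choose underlying parameters so the truncated distribution reproduces the
# target mean and sd. The mean is weighted heavily (some target sds are
# geometrically unreachable inside narrow bounds, so the sd term is best
# effort), and parameter regions where the bounds retain almost no
# probability mass are penalised: they would make rejection sampling
# intractable and correspond to degenerate edge-piling shapes anyway.
calibrate_trunc <- function(target_mean, target_sd, a, b,
                            family = c("normal", "lognormal")) {
  family <- match.arg(family)
  moments <- if (family == "normal") tnorm_moments else tlnorm_moments
  start <- if (family == "normal") {
    c(target_mean, log(target_sd))
  } else {
    s2 <- log(1 + (target_sd / target_mean)^2)
    c(log(target_mean) - s2 / 2, log(sqrt(s2)))
  }
  obj <- function(p) {
    mo <- moments(p[1], exp(p[2]), a, b)
    if (any(!is.finite(mo))) return(1e6)
    25 * ((mo[1] - target_mean) / target_sd)^2 +
      ((mo[2] - target_sd) / target_sd)^2 +
      1e4 * max(0, 0.2 - mo[3])^2
  }
  p <- stats::optim(start, obj, control = list(maxit = 2000, reltol = 1e-12))$par
  mo <- moments(p[1], exp(p[2]), a, b)
  if (!is.finite(mo[3]) || mo[3] < 0.05) {
    # fall back to plain moment matching rather than sample from a sliver
    p <- start
  }
  list(location = p[1], scale = exp(p[2]))
}

# mean/sd-calibrated truncated normal sampler
rnorm_trunc_cal <- function(n, target_mean, target_sd, lower, upper) {
  if (target_sd == 0) return(rnorm_trunc(n, target_mean, 0, lower, upper))
  p <- calibrate_trunc(target_mean, target_sd, lower, upper, "normal")
  rnorm_trunc(n, p$location, p$scale, lower, upper)
}

# lognormal draws with arithmetic mean `mean` and coefficient of variation
# `cv`; mean 1 noise comes from mean = 1
rlnorm_cv <- function(n, mean = 1, cv = 0) {
  if (cv == 0) return(rep(mean, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column %s", what, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  invisible(df)
}

check_state <- function(state) {
  bad <- setdiff(unique(state), c("raw", "fried"))
  if (length(bad) > 0) {
    stop(sprintf("state must be 'raw' or 'fried', got: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(state)
}
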