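# Rate estimation: crude and age/sex-specific incidence per 100,000
# person-years with exact Poisson intervals, direct standardization with a
# binomial-approximation standard error, standardized rate ratios, pooled
# regions, and Wilson-interval point prevalence.

#' Construct a rate estimate
#'
#' @param rate,ci_low,ci_high Rate and interval, per 100,000.
#' @param ci_level Nominal coverage, e.g. 0.95.
#' @param method One of `"poisson_exact"`, `"binomial_se"`, `"wilson"`.
#' @param n_events Event count (possibly fractional after weighting).
#' @param person_years Denominator person-years (or persons).
#' @param se Optional standard error on the per-100,000 scale.
#' @return A list of class `rate_estimate`.
#' @export
rate_estimate <- function(rate, ci_low, ci_high, ci_level, method,
                          n_events = NA_real_, person_years = NA_real_,
                          se = NA_real_) {
  stopifnot(rate >= 0, ci_low <= rate + 1e-9, rate <= ci_high + 1e-9)
  structure(list(rate = rate, ci_low = ci_low, ci_high = ci_high,
                 ci_level = ci_level, method = method, n_events = n_events,
                 person_years = person_years, se = se),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%.2f (%d%% CI %.2f-%.2f) per 100,000 [%s]\n",
              x$rate, round(100 * x$ci_level), x$ci_low, x$ci_high,
              x$method))
  invisible(x)
}

#' Exact Poisson confidence limits for an event count
#'
#' Two-sided exact limits for the mean of a Poisson count: the lower limit
#' is the mean whose upper tail probability at `k` equals `(1 - level)/2`
#' (zero when `k = 0`), the upper limit the mean whose lower tail equals
#' the same. Fractional counts, which arise from sector weighting and the
#' 0.5 substitution, are handled through the continuous chi-square
#' formulation: `low = qchisq(a/2, 2k)/2`, `high = qchisq(1 - a/2, 2k + 2)/2`.
#'
#' @param k Nonnegative event count(s), possibly fractional.
#' @param level Nominal two-sided coverage (default 0.95).
#' @return A two-column matrix (`low`, `high`) of count-scale limits.
#' @export
#' @examples
#' poisson_exact_ci(10)   # approx (4.795, 18.390)
poisson_exact_ci <- function(k, level = 0.95) {
  if (any(k < 0)) stop("event count k must be nonnegative")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  a <- 1 - level
  low <- ifelse(k == 0, 0, stats::qchisq(a / 2, 2 * k) / 2)
  high <- stats::qchisq(1 - a / 2, 2 * k + 2) / 2
  cbind(low = low, high = high)
}

#' Crude rate per 100,000 person-years with exact Poisson interval
#'
#' @param n_events Event count (possibly fractional).
#' @param person_years Person-years at risk; must be positive.
#' @param level Nominal coverage.
#' @return A `rate_estimate` with method `"poisson_exact"`.
#' @export
crude_rate <- function(n_events, person_years, level = 0.95) {
  if (person_years <= 0) stop("person_years must be positive")
  ci <- poisson_exact_ci(n_events, level)
  rate_estimate(
    rate = n_events / person_years * 1e5,
    ci_low = unname(ci[1, "low"]) / person_years * 1e5,
    ci_high = unname(ci[1, "high"]) / person_years * 1e5,
    ci_level = level, method = "poisson_exact",
    n_events = n_events, person_years = person_years
  )
}

#' Age- and sex-specific rates from a count grid and population grid
#'
#' Each cell's person-years are the mid-period population multiplied by the
#' study length; each cell rate carries an exact Poisson interval.
#'
#' @param counts A `count_table` (typically after [substitute_zero_cells()]).
#' @param pop Data frame with `sex`, `age_band`, `count` giving mid-period
#'   population per cell; all cells used as denominators must be positive.
#' @param study_years Study period length in years (e.g. 14 for 2004-2017).
#' @param level Nominal coverage.
#' @return A data frame of class `rate_table`: `sex`, `age_band`,
#'   `n_events`, `person_years`, `rate`, `ci_low`, `ci_high` over the full
#'   16 x 2 grid, with `study_years` and `ci_level` attributes.
#' @export
specific_rates <- function(counts, pop, study_years, level = 0.95) {
  if (study_years <= 0) stop("study_years must be positive")
  key <- paste(counts$sex, counts$age_band)
  idx <- match(key, paste(pop$sex, pop$age_band))
  if (anyNA(idx)) {
    stop("population grid lacks cell(s): ",
         paste(key[is.na(idx)], collapse = ", "))
  }
  denom <- pop$count[idx]
  bad <- which(denom <= 0)
  if (length(bad)) {
    stop("zero population in cell(s): ", paste(key[bad], collapse = ", "))
  }
  py <- denom * study_years
  ci <- poisson_exact_ci(counts$count, level)
  out <- data.frame(
    sex = counts$sex, age_band = counts$age_band,
    n_events = counts$count, person_years = py,
    rate = counts$count / py * 1e5,
    ci_low = ci[, "low"] / py * 1e5,
    ci_high = ci[, "high"] / py * 1e5,
    stringsAsFactors = FALSE
  )
  attr(out, "study_years") <- study_years
  attr(out, "ci_level") <- level
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Standard error and interval for a directly standardized rate
#'
#' Treats the standardized rate as a binomial proportion `p = rate / 1e5`
#' observed on the standard population total, so `se = sqrt(p (1 - p) / n)`
#' with a symmetric normal interval, floored at zero.
#'
#' @param std_rate Standardized rate per 100,000.
#' @param effective_n Standard population total backing the rate.
#' @param level Nominal coverage.
#' @return List with `se`, `ci_low`, `ci_high`, all per 100,000.
#' @export
standardized_rate_se <- function(std_rate, effective_n, level = 0.95) {
  p <- std_rate / 1e5
  if (p < 0 || p > 1) stop("std_rate must map to a proportion in [0, 1]")
  if (effective_n <= 0) stop("effective_n must be positive")
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(p * (1 - p) / effective_n)
  list(se = se * 1e5,
       ci_low = max(0, p - z * se) * 1e5,
       ci_high = (p + z * se) * 1e5)
}

#' Directly standardized rates
#'
#' Weights the study's band-specific rates by a standard population's
#' structure: within each sex the standardized rate is the standard-count
#' weighted mean of band rates, and the overall rate weights the
#' sex-specific band rates by the sex-specific standard counts. Intervals
#' come from [standardized_rate_se()] with the relevant standard total as
#' the effective denominator.
#'
#' @param rates A `rate_table` from [specific_rates()].
#' @param standard Data frame with `sex`, `age_band`, `count`: the
#'   standard population structure (e.g. a national mid-year estimate).
#' @param level Nominal coverage.
#' @return List of `rate_estimate`s: `male`, `female`, `overall`, each
#'   with method `"binomial_se"`.
#' @export
direct_standardize <- function(rates, standard, level = 0.95) {
  idx <- match(paste(rates$sex, rates$age_band),
               paste(standard$sex, standard$age_band))
  if (anyNA(idx)) {
    stop("standard population lacks cell(s): ",
         paste(paste(rates$sex, rates$age_band)[is.na(idx)], collapse = ", "))
  }
  w <- standard$count[idx]
  if (any(w < 0) || sum(w) <= 0) stop("standard weights must be nonnegative with positive total")
  one <- function(sel) {
    std <- sum(rates$rate[sel] * w[sel]) / sum(w[sel])
    ci <- standardized_rate_se(std, sum(w[sel]), level)
    rate_estimate(std, ci$ci_low, ci$ci_high, level, "binomial_se",
                  n_events = sum(rates$n_events[sel]),
                  person_years = sum(rates$person_years[sel]),
                  se = ci$se)
  }
  list(male = one(rates$sex == "male"),
       female = one(rates$sex == "female"),
       overall = one(rep(TRUE, nrow(rates))))
}

#' Standardized rate ratio of two regions
#'
#' Ratio of two directly standardized rates with a log-normal interval:
#' the delta-method standard error of the log ratio combines the two
#' rates' standard errors. Standard errors are taken from the estimates'
#' `se` fields, or recovered from their interval widths when absent.
#'
#' @param r1,r2 `rate_estimate`s (numerator, denominator).
#' @param level Nominal coverage.
#' @return List with `ratio`, `ci_low`, `ci_high`, `ci_level`.
#' @export
standardized_rate_ratio <- function(r1, r2, level = 0.95) {
  if (r2$rate <= 0) stop("denominator rate must be positive")
  z <- stats::qnorm(1 - (1 - level) / 2)
  se_of <- function(r) {
    if (!is.null(r$se) && is.finite(r$se)) r$se
    else (r$ci_high - r$ci_low) / (2 * z)
  }
  ratio <- r1$rate / r2$rate
  se_log <- sqrt((se_of(r1) / r1$rate)^2 + (se_of(r2) / r2$rate)^2)
  list(ratio = ratio,
       ci_low = ratio * exp(-z * se_log),
       ci_high = ratio * exp(z * se_log),
       ci_level = level)
}

#' Pool two regions' counts and populations
#'
#' Cellwise sums the raw (pre-substitution) counts and the populations,
#' re-applies the 0.5 substitution only to cells still empty after
#' pooling, and recomputes rates on the pooled person-years.
#'
#' @param counts_a,counts_b `count_table`s on the shared grid, before any
#'   zero-cell substitution.
#' @param pop_a,pop_b Population grids (`sex`, `age_band`, `count`).
#' @param study_years Shared study period length in years.
#' @param level Nominal coverage.
#' @param substitute Apply [substitute_zero_cells()] after pooling
#'   (default `TRUE`).
#' @return A `rate_table` on the pooled data.
#' @export
pool_regions <- function(counts_a, pop_a, counts_b, pop_b, study_years,
                         level = 0.95, substitute = TRUE) {
  align <- function(a, b, what) {
    idx <- match(paste(a$sex, a$age_band), paste(b$sex, b$age_band))
    if (anyNA(idx) || length(idx) != nrow(b)) stop(what, " grids do not match")
    b$count[idx]
  }
  pooled <- counts_a
  pooled$count <- counts_a$count + align(counts_a, counts_b, "count")
  if (substitute) pooled <- substitute_zero_cells(pooled)
  pop <- pop_a[, c("sex", "age_band", "count")]
  pop$count <- pop_a$count + align(pop_a, pop_b, "population")
  specific_rates(pooled, pop, study_years, level)
}

#' Wilson score interval for a proportion
#'
#' @param k Success count(s), `0 <= k <= n`.
#' @param n Trial count(s), positive.
#' @param level Nominal coverage.
#' @return Two-column matrix (`low`, `high`) of proportions in `[0, 1]`.
#' @export
#' @examples
#' wilson_ci(5, 100)   # approx (0.0216, 0.1118)
wilson_ci <- function(k, n, level = 0.95) {
  if (any(n <= 0)) stop("n must be positive")
  if (any(k < 0) || any(k > n)) stop("k must lie in [0, n]")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  cbind(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' Point prevalence per 100,000 persons
#'
#' @param n_alive Cases alive with the disease on the prevalence date.
#' @param population Population on that date; must be positive.
#' @param date_label Optional label (e.g. `"2010-06-30"`) stored on the
#'   estimate.
#' @param level Nominal coverage.
#' @return A `rate_estimate` with method `"wilson"`, per 100,000 persons.
#' @export
point_prevalence <- function(n_alive, population, date_label = NULL,
                             level = 0.95) {
  if (population <= 0) stop("population must be positive")
  ci <- wilson_ci(n_alive, population, level)
  est <- rate_estimate(
    rate = n_alive / population * 1e5,
    ci_low = unname(ci[1, "low"]) * 1e5,
    ci_high = unname(ci[1, "high"]) * 1e5,
    ci_level = level, method = "wilson",
    n_events = n_alive, person_years = population
  )
  est$date <- date_label
  est
}
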