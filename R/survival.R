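# Disease-duration estimation: from-scratch Kaplan-Meier product-limit
# curves, median survival with a Brookmeyer-Crowley-style interval on the
# complementary log-log scale, and restricted mean survival time, overall
# and by age cohort.

#' Kaplan-Meier product-limit fit
#'
#' Nonparametric survival estimate under right-censoring. The risk set at
#' each distinct observed time counts subjects whose time is at or beyond
#' it, so events and censorings tied at the same time are resolved
#' events-first (censored subjects remain at risk for that time's events).
#' Pointwise intervals use the Greenwood variance on the complementary
#' log-log scale.
#'
#' @param time Positive observation times (months here).
#' @param event 1 (or `TRUE`) if the event (death) occurred, 0 if censored.
#' @param level Nominal pointwise coverage for the confidence band.
#' @return Data frame of class `km_curve`, one row per distinct observed
#'   time: `time`, `n_risk`, `n_event`, `n_censor`, `surv`, `ci_low`,
#'   `ci_high`; attributes `n` and `level`.
#' @export
km_fit <- function(time, event, level = 0.95) {
  event <- as.integer(event)
  if (length(time) == 0) stop("survival sample is empty")
  if (length(event) != length(time)) stop("time and event lengths differ")
  if (any(is.na(time)) || any(time <= 0)) stop("times must be positive and non-missing")
  if (!all(event %in% c(0L, 1L))) stop("event must be 0/1")

  tt <- sort(unique(time))
  n_risk <- vapply(tt, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(tt, function(t) sum(time == t & event == 1L), numeric(1))
  n_censor <- vapply(tt, function(t) sum(time == t & event == 0L), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)

  # Greenwood variance of log S, then complementary log-log band
  gw <- cumsum(ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ok <- surv > 0 & surv < 1
  se_cll <- rep(NA_real_, length(tt))
  se_cll[ok] <- sqrt(gw[ok]) / abs(log(surv[ok]))
  ci_low <- ci_high <- rep(NA_real_, length(tt))
  ci_low[ok] <- surv[ok]^exp(z * se_cll[ok])
  ci_high[ok] <- surv[ok]^exp(-z * se_cll[ok])
  ci_low[surv == 0] <- 0
  ci_high[surv == 0] <- 0

  out <- data.frame(time = tt, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, surv = surv,
                    ci_low = ci_low, ci_high = ci_high)
  attr(out, "n") <- length(time)
  attr(out, "level") <- level
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Median survival from a Kaplan-Meier curve
#'
#' The median is the smallest event time at which the survival estimate
#' falls to 0.5 or below. The interval inverts the pointwise confidence
#' band through the same definition (Brookmeyer-Crowley approach on the
#' complementary log-log scale): the lower limit is the first time the
#' band's lower edge reaches 0.5, the upper limit the first time its upper
#' edge does. The reported standard error is the interval width divided by
#' twice the normal quantile. A curve that never reaches 0.5 yields an
#' undefined (flagged) median, which is a legal result, not an error.
#'
#' @param curve A `km_curve` from [km_fit()].
#' @param level Nominal coverage; defaults to the curve's band level.
#' @return List with `median`, `se`, `ci_low`, `ci_high`, `defined`.
#' @export
km_median <- function(curve, level = attr(curve, "level") %||% 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  first_cross <- function(vals) {
    i <- which(!is.na(vals) & vals <= 0.5 + 1e-12)
    if (length(i)) curve$time[min(i)] else NA_real_
  }
  ev <- curve$n_event > 0
  med <- {
    i <- which(ev & curve$surv <= 0.5 + 1e-12)
    if (length(i)) curve$time[min(i)] else NA_real_
  }
  lo <- first_cross(curve$ci_low)
  hi <- first_cross(curve$ci_high)
  se <- if (is.na(lo) || is.na(hi)) NA_real_ else (hi - lo) / (2 * z)
  list(median = med, se = se, ci_low = lo, ci_high = hi,
       defined = !is.na(med))
}

#' Restricted mean survival time
#'
#' Area under the Kaplan-Meier curve from 0 up to `tau` (default: the
#' largest observed time), with the standard Greenwood-based variance for
#' the area.
#'
#' @param curve A `km_curve`.
#' @param tau Restriction time in the curve's units; must be positive.
#' @return List with `mean`, `se`, `tau`, and normal-interval `ci_low`,
#'   `ci_high` at the curve's band level.
#' @export
km_mean_restricted <- function(curve, tau = NULL) {
  tau <- tau %||% max(curve$time)
  if (tau <= 0) stop("tau must be positive")
  keep <- curve$time <= tau
  knots <- c(0, curve$time[keep])
  sv <- c(1, curve$surv[keep])
  widths <- diff(c(knots, tau))
  segs <- sv * widths
  total <- sum(segs)
  # A[i] = area under S from the i-th retained time to tau
  cum_to_knot <- cumsum(segs)   # entry j: area from 0 up to knots[j + 1] (or tau)
  A <- total - cum_to_knot[-length(cum_to_knot)]
  d <- curve$n_event[keep]
  n <- curve$n_risk[keep]
  term <- ifelse(d > 0 & n > d, A^2 * d / (n * (n - d)), 0)
  se <- sqrt(sum(term))
  z <- stats::qnorm(1 - (1 - (attr(curve, "level") %||% 0.95)) / 2)
  list(mean = total, se = se, tau = tau,
       ci_low = total - z * se, ci_high = total + z * se)
}

#' Disease duration in whole months
#'
#' Duration runs from symptom onset to death or last follow-up, rounded
#' down to whole months (30.4375 days per month) with a floor of one month
#' so every duration is positive.
#'
#' @param cases A `case_records` data frame with `date_of_onset`,
#'   `end_date`, `end_event`.
#' @return Data frame with `duration_months`, `event` (1 = died),
#'   `age_at_diagnosis`, and `cohort`.
#' @export
case_durations <- function(cases) {
  if (anyNA(cases$date_of_onset)) {
    stop("cases with missing date_of_onset; apply_exclusions(purpose = \"survival\") first")
  }
  months <- floor(as.numeric(cases$end_date - cases$date_of_onset) / 30.4375)
  data.frame(
    duration_months = pmax(1, months),
    event = as.integer(cases$end_event == "died"),
    age_at_diagnosis = cases$age_at_diagnosis,
    cohort = cohort_of_age(cases$age_at_diagnosis),
    stringsAsFactors = FALSE
  )
}

#' Kaplan-Meier duration estimates by age cohort
#'
#' Fits the product-limit estimator within each age cohort (`<40`,
#' `40-79`, `80+`, by age at diagnosis) and overall, reporting the median
#' with its interval and the restricted mean (up to each group's largest
#' observed time). A cohort with fewer than two subjects is flagged with a
#' warning and its estimates reported as-is.
#'
#' @param cases Either a `case_records` data frame (durations derived via
#'   [case_durations()]) or a data frame already carrying
#'   `duration_months`, `event`, and `cohort`.
#' @param level Nominal coverage.
#' @return Data frame of class `duration_table`: one row per cohort plus
#'   `overall`, with `n`, `n_events`, `median_months`, `median_se`,
#'   `median_ci_low`, `median_ci_high`, `mean_months`, `mean_se`,
#'   `mean_ci_low`, `mean_ci_high`, `flagged`.
#' @export
survival_by_age_cohort <- function(cases, level = 0.95) {
  df <- if (all(c("duration_months", "event", "cohort") %in% names(cases))) {
    cases
  } else {
    case_durations(cases)
  }
  groups <- c(duration_cohorts(), "overall")
  rows <- lapply(groups, function(g) {
    sel <- if (g == "overall") rep(TRUE, nrow(df)) else df$cohort == g
    n <- sum(sel)
    flagged <- n < 2
    if (flagged) {
      warning("cohort ", g, " has fewer than 2 subjects; estimates unstable")
    }
    if (n == 0) {
      return(data.frame(cohort = g, n = 0, n_events = 0,
                        median_months = NA_real_, median_se = NA_real_,
                        median_ci_low = NA_real_, median_ci_high = NA_real_,
                        mean_months = NA_real_, mean_se = NA_real_,
                        mean_ci_low = NA_real_, mean_ci_high = NA_real_,
                        flagged = TRUE))
    }
    fit <- km_fit(df$duration_months[sel], df$event[sel], level)
    med <- km_median(fit, level)
    mn <- km_mean_restricted(fit)
    data.frame(cohort = g, n = n, n_events = sum(df$event[sel]),
               median_months = med$median, median_se = med$se,
               median_ci_low = med$ci_low, median_ci_high = med$ci_high,
               mean_months = mn$mean, mean_se = mn$se,
               mean_ci_low = mn$ci_low, mean_ci_high = mn$ci_high,
               flagged = flagged)
  })
  out <- do.call(rbind, rows)
  attr(out, "ci_level") <- level
  class(out) <- c("duration_table", "data.frame")
  out
}

#' Build a duration table from known medians
#'
#' Constructs the minimal `duration_table` the projection stage needs from
#' per-cohort median durations, e.g. published estimates or generator
#' ground truth.
#'
#' @param medians Named numeric vector of median months with names
#'   `"<40"`, `"40-79"`, `"80+"` and optionally `"overall"`.
#' @return A `duration_table` with the median column populated.
#' @export
duration_table <- function(medians) {
  need <- duration_cohorts()
  if (!all(need %in% names(medians))) {
    stop("medians must name cohorts: ", paste(need, collapse = ", "))
  }
  if (any(medians <= 0)) stop("median durations must be positive")
  grp <- c(need, if ("overall" %in% names(medians)) "overall")
  out <- data.frame(cohort = grp, n = NA_real_, n_events = NA_real_,
                    median_months = as.numeric(medians[grp]),
                    median_se = NA_real_, median_ci_low = NA_real_,
                    median_ci_high = NA_real_, mean_months = NA_real_,
                    mean_se = NA_real_, mean_ci_low = NA_real_,
                    mean_ci_high = NA_real_, flagged = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("duration_table", "data.frame")
  out
}
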