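# Projection: apply fixed age/sex-specific incidence rates to population
# projections year by year, convert incidence to prevalence through median
# disease duration, and transform durations under hypothetical treatment
# scenarios (including a life-table "halted progression" scenario).

check_projection <- function(proj) {
  need <- c("year", "sex", "age", "count")
  if (!all(need %in% names(proj))) {
    stop("projection must have columns ", paste(need, collapse = ", "))
  }
  if (any(proj$count < 0)) stop("projected counts must be nonnegative")
  invisible(proj)
}

resolve_years <- function(proj, years) {
  have <- sort(unique(proj$year))
  if (is.null(years)) return(have)
  missing <- setdiff(years, have)
  if (length(missing)) {
    stop("year(s) outside projection coverage: ",
         paste(missing, collapse = ", "))
  }
  sort(years)
}

band_pop <- function(proj, years) {
  pj <- proj[proj$year %in% years & proj$age >= 15, , drop = FALSE]
  pj$age_band <- age_to_band(pj$age)
  stats::aggregate(count ~ year + sex + age_band, data = pj, FUN = sum)
}

#' Project annual incident cases
#'
#' Applies constant age/sex-specific incidence rates to a population
#' projection, year by year: expected incident cases in a cell are the
#' cell rate per 100,000 times the projected cell population. Single-year
#' ages are aggregated to the 5-year band scheme; ages under 15 contribute
#' no cases.
#'
#' @param rates A `rate_table` (per 100,000 person-years).
#' @param proj Population projection: data frame `year`, `sex`, `age`
#'   (single years), `count`.
#' @param years Calendar years to project; default all years present.
#'   Years absent from the projection are an error.
#' @return Data frame of class `incidence_projection`: `year`, `sex`,
#'   `age_band`, `population`, `cases`.
#' @export
project_incidence <- function(rates, proj, years = NULL) {
  check_projection(proj)
  years <- resolve_years(proj, years)
  agg <- band_pop(proj, years)
  idx <- match(paste(agg$sex, agg$age_band),
               paste(rates$sex, rates$age_band))
  if (anyNA(idx)) {
    stop("rate table lacks cell(s): ",
         paste(unique(paste(agg$sex, agg$age_band)[is.na(idx)]), collapse = ", "))
  }
  out <- data.frame(year = agg$year, sex = agg$sex, age_band = agg$age_band,
                    population = agg$count,
                    cases = rates$rate[idx] / 1e5 * agg$count,
                    stringsAsFactors = FALSE)
  out <- out[order(out$year, out$sex, match(out$age_band, als_age_bands())), ]
  rownames(out) <- NULL
  class(out) <- c("incidence_projection", "data.frame")
  out
}

#' Per-year incident totals by sex and overall
#'
#' @param ip An `incidence_projection` from [project_incidence()].
#' @return Data frame `year`, `sex` (male/female/overall), `cases`; the
#'   overall row is the exact sum of the two sex rows.
#' @export
incidence_totals <- function(ip) {
  by_sex <- stats::aggregate(cases ~ year + sex, data = ip, FUN = sum)
  overall <- stats::aggregate(cases ~ year, data = ip, FUN = sum)
  overall$sex <- "overall"
  out <- rbind(by_sex, overall[, c("year", "sex", "cases")])
  out[order(out$year, match(out$sex, c("male", "female", "overall"))), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

# Shared prevalence engine: `duration_fn(year, sex, band)` returns the
# effective mean duration in months for that stratum-year.
project_prevalence_engine <- function(rates, proj, duration_fn, years,
                                      scenario) {
  check_projection(proj)
  years <- resolve_years(proj, years)
  agg <- band_pop(proj, years)
  idx <- match(paste(agg$sex, agg$age_band),
               paste(rates$sex, rates$age_band))
  if (anyNA(idx)) stop("rate table lacks cells needed by the projection")
  dur <- mapply(duration_fn, agg$year, agg$sex, agg$age_band)
  prev_cells <- rates$rate[idx] / 1e5 * agg$count * dur / 12

  denom_sex <- stats::aggregate(count ~ year + sex, data = proj[proj$year %in% years, ], FUN = sum)
  cells <- data.frame(year = agg$year, sex = agg$sex, prevalent_cases = prev_cells)
  num_sex <- stats::aggregate(prevalent_cases ~ year + sex, data = cells, FUN = sum)
  m <- merge(num_sex, denom_sex, by = c("year", "sex"))
  overall <- stats::aggregate(cbind(prevalent_cases, count) ~ year, data = m, FUN = sum)
  overall$sex <- "overall"
  out <- rbind(m[, c("year", "sex", "prevalent_cases", "count")],
               overall[, c("year", "sex", "prevalent_cases", "count")])
  names(out)[names(out) == "count"] <- "population"
  out$prevalence_per_100k <- out$prevalent_cases / out$population * 1e5
  out$scenario <- scenario
  out <- out[order(out$year, match(out$sex, c("male", "female", "overall"))),
             c("scenario", "year", "sex", "prevalent_cases", "population",
               "prevalence_per_100k")]
  rownames(out) <- NULL
  class(out) <- c("prevalence_series", "data.frame")
  out
}

#' Project annual prevalence from incidence and median duration
#'
#' Expected prevalent cases in a cell-year are incident cases (rate times
#' projected population) multiplied by the cell's median disease duration
#' in years; the three duration cohorts map onto bands via
#' [band_to_cohort()]. Per-100,000 prevalence divides each stratum's
#' prevalent count by the same year's full projected population (all
#' ages) for that stratum.
#'
#' @param rates A `rate_table`.
#' @param proj Population projection (`year`, `sex`, `age`, `count`).
#' @param durations A `duration_table` with positive `median_months` for
#'   every cohort; a missing cohort is an error.
#' @param years Years to project; default all present.
#' @param scenario Label stored on the output (default `"baseline"`).
#' @return A `prevalence_series`: `scenario`, `year`, `sex`
#'   (male/female/overall), `prevalent_cases`, `population`,
#'   `prevalence_per_100k`.
#' @export
project_prevalence <- function(rates, proj, durations, years = NULL,
                               scenario = "baseline") {
  med <- cohort_medians(durations)
  project_prevalence_engine(
    rates, proj,
    function(year, sex, band) med[[band_to_cohort(band)]],
    years, scenario
  )
}

cohort_medians <- function(durations) {
  need <- duration_cohorts()
  idx <- match(need, durations$cohort)
  if (anyNA(idx)) {
    stop("duration table lacks cohort(s): ",
         paste(need[is.na(idx)], collapse = ", "))
  }
  med <- durations$median_months[idx]
  if (anyNA(med) || any(med <= 0)) {
    stop("median duration missing or non-positive for cohort(s): ",
         paste(need[is.na(med) | med <= 0], collapse = ", "))
  }
  stats::setNames(as.list(med), need)
}

#' Define a treatment scenario
#'
#' A scenario lengthens disease duration for a fraction of patients: a
#' fixed additional number of months (`add_months`), a multiplicative
#' survival gain (`multiply`), or replacement of disease survival by the
#' period life expectancy for the patient's age, sex and year
#' (`life_table`, i.e. progression halted).
#'
#' @param name Scenario label.
#' @param affected_fraction Fraction of patients affected, in `[0, 1]`.
#' @param transform One of `"add_months"`, `"multiply"`, `"life_table"`.
#' @param amount Months added (for `add_months`, `>= 0`) or survival
#'   multiplier (for `multiply`, `> 0`); ignored for `life_table`.
#' @param year_cap Last calendar year the scenario can be evaluated for
#'   (`life_table` only; limited by life-table coverage).
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(name, affected_fraction,
                          transform = c("add_months", "multiply", "life_table"),
                          amount = NULL, year_cap = NULL) {
  transform <- match.arg(transform)
  if (affected_fraction < 0 || affected_fraction > 1) {
    stop("affected_fraction must lie in [0, 1]")
  }
  if (transform == "add_months" && (is.null(amount) || amount < 0)) {
    stop("add_months scenario needs amount >= 0")
  }
  if (transform == "multiply" && (is.null(amount) || amount <= 0)) {
    stop("multiply scenario needs amount > 0")
  }
  structure(list(name = name, affected_fraction = affected_fraction,
                 transform = transform, amount = amount,
                 year_cap = year_cap),
            class = "scenario_spec")
}

#' The four modelled treatment scenarios
#'
#' * `s1` - a riluzole-equivalent drug adding 3 months of median survival
#'   for every patient.
#' * `s2` - a gene therapy multiplying median survival by 1.5 for the 4%
#'   of patients carrying a *SOD1* mutation.
#' * `s3` - the same 1.5-fold gain for the 10% carrying a *C9orf72*
#'   mutation.
#' * `s4` - progression halted for the *C9orf72* 10%, whose survival
#'   reverts to period life expectancy for their age, sex and year
#'   (evaluable up to the life-table horizon, 2066).
#'
#' @return Named list of `scenario_spec`s.
#' @export
als_scenarios <- function() {
  list(
    s1 = scenario_spec("s1", 1, "add_months", 3),
    s2 = scenario_spec("s2", 0.04, "multiply", 1.5),
    s3 = scenario_spec("s3", 0.10, "multiply", 1.5),
    s4 = scenario_spec("s4", 0.10, "life_table", year_cap = 2066)
  )
}

#' Effective duration multiplier implied by a scenario
#'
#' Population-average duration under a scenario, as a multiple of the
#' baseline median: with affected fraction `f`, a `multiply` scenario with
#' gain `m` gives `1 - f + f m` (cohort-independent); an `add_months`
#' scenario with increment `d` gives `1 - f + f (median + d) / median`;
#' a `life_table` scenario with cohort-representative life expectancy `E`
#' (months) gives `1 - f + f E / median`.
#'
#' @param spec A `scenario_spec`.
#' @param median_months Baseline median duration(s) in months; vectorized.
#' @param life_expectancy_months Required for `life_table` scenarios.
#' @return Numeric multiplier(s), same length as `median_months`.
#' @export
#' @examples
#' s <- als_scenarios()
#' scenario_multiplier(s$s3, 34)   # 1.05
scenario_multiplier <- function(spec, median_months,
                                life_expectancy_months = NULL) {
  if (any(median_months <= 0)) stop("median duration must be positive")
  f <- spec$affected_fraction
  switch(spec$transform,
    multiply = rep_len(1 - f + f * spec$amount, length(median_months)),
    add_months = 1 - f + f * (median_months + spec$amount) / median_months,
    life_table = {
      if (is.null(life_expectancy_months)) {
        stop("life_table scenario needs life_expectancy_months")
      }
      1 - f + f * life_expectancy_months / median_months
    }
  )
}

#' Period life expectancy lookup
#'
#' @param life Life table: data frame `year`, `sex`, `age`,
#'   `expected_years` (period expected remaining years of life).
#' @param age Age in whole years (a band's representative age when called
#'   per band).
#' @param sex `"male"` or `"female"`.
#' @param year Calendar year; years outside the table are an error (no
#'   extrapolation).
#' @return Expected remaining life in months.
#' @export
life_expectancy_lookup <- function(life, age, sex, year) {
  if (!year %in% life$year) {
    stop("life table does not cover year ", year, "; no extrapolation")
  }
  hit <- life$year == year & life$sex == sex & life$age == age
  if (!any(hit)) {
    stop("life table has no entry for age ", age, ", sex ", sex,
         ", year ", year)
  }
  life$expected_years[which(hit)[1]] * 12
}

#' Prevalence series under a treatment scenario
#'
#' Recomputes the prevalence projection with scenario-transformed
#' durations. `multiply` scenarios scale every cohort's median by the
#' closed-form multiplier; `add_months` scenarios either add the increment
#' to each cohort's median (`scenario1_mode = "per_cohort"`, default) or
#' scale all cohorts by `(overall median + d) / overall median`
#' (`"overall_median"`, requires an `overall` row in `durations`).
#' `life_table` scenarios give the affected fraction, per year, sex and
#' band, the period life expectancy at the band's representative age
#' ([band_midpoint()]); the unaffected fraction keeps the baseline
#' median. Requesting a `life_table` scenario beyond its `year_cap` is an
#' error; with `years = NULL` the projection runs over the years the
#' projection table covers up to the cap.
#'
#' @param rates A `rate_table`.
#' @param proj Population projection.
#' @param durations Baseline `duration_table`.
#' @param spec A `scenario_spec`.
#' @param life Life table, required for `life_table` scenarios.
#' @param years Years to project.
#' @param scenario1_mode How `add_months` scenarios use the medians; see
#'   above.
#' @return A `prevalence_series` labelled with the scenario name.
#' @export
apply_scenario <- function(rates, proj, durations, spec, life = NULL,
                           years = NULL,
                           scenario1_mode = c("per_cohort", "overall_median")) {
  scenario1_mode <- match.arg(scenario1_mode)
  med <- cohort_medians(durations)

  if (spec$transform == "life_table") {
    if (is.null(life)) stop("life_table scenario requires a life table")
    cap <- spec$year_cap %||% max(life$year)
    if (is.null(years)) {
      years <- sort(unique(proj$year))
      years <- years[years <= cap]
    } else if (any(years > cap)) {
      stop("life_table scenario only evaluable up to year ", cap)
    }
    f <- spec$affected_fraction
    dur_fn <- function(year, sex, band) {
      E <- life_expectancy_lookup(life, band_midpoint(band), sex, year)
      (1 - f) * med[[band_to_cohort(band)]] + f * E
    }
    return(project_prevalence_engine(rates, proj, dur_fn, years, spec$name))
  }

  new_med <- med
  if (spec$transform == "add_months" && scenario1_mode == "overall_median") {
    ov <- durations$median_months[durations$cohort == "overall"]
    if (!length(ov) || is.na(ov)) {
      stop("overall_median mode requires an overall median in durations")
    }
    mult <- scenario_multiplier(spec, ov)
    for (g in names(new_med)) new_med[[g]] <- med[[g]] * mult
  } else {
    for (g in names(new_med)) {
      new_med[[g]] <- med[[g]] * scenario_multiplier(spec, med[[g]])
    }
  }
  project_prevalence_engine(
    rates, proj,
    function(year, sex, band) new_med[[band_to_cohort(band)]],
    years, spec$name
  )
}
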