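# Projection: incidence under demographic change, duration-driven
# prevalence, treatment scenarios and life-table lookups.

mk_flat_proj <- function(years = 2020:2022, count = 1000) {
  expand.grid(year = years, sex = c("male", "female"), age = 0:100,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE) |>
    transform(count = count)
}

flat_rate_table <- function(rate = 2) {
  rt <- count_table()[, c("sex", "age_band")]
  rt$n_events <- NA_real_; rt$person_years <- NA_real_
  rt$rate <- rate; rt$ci_low <- NA_real_; rt$ci_high <- NA_real_
  class(rt) <- c("rate_table", "data.frame")
  rt
}

test_that("incident cases are rate x population, constant when population is", {
  proj <- mk_flat_proj()
  rt <- flat_rate_table(2)
  ip <- project_incidence(rt, proj)
  tot <- incidence_totals(ip)
  # constant population -> constant incident counts across years
  ov <- tot$cases[tot$sex == "overall"]
  expect_true(all(abs(ov - ov[1]) < 1e-9))
  # one cell by hand: rate 2 per 1e5 on 5 x 1000 persons per band
  cell <- ip$year == 2020 & ip$sex == "male" & ip$age_band == "20-24"
  expect_equal(ip$cases[cell], 2 / 1e5 * 5000)
  # totals conserve: overall = male + female, exactly
  m <- tot$cases[tot$sex == "male"]
  f <- tot$cases[tot$sex == "female"]
  expect_identical(ov, m + f)
  expect_error(project_incidence(rt, proj, years = 1999),
               "outside projection coverage")
})

test_that("prevalence multiplies incidence by duration in years", {
  proj <- mk_flat_proj(years = 2020)
  rt <- flat_rate_table(2)
  dur <- duration_table(c("<40" = 34, "40-79" = 34, "80+" = 34))
  ps <- project_prevalence(rt, proj, dur)
  # 86 adult ages x 2 sexes x 1000 persons at rate 2/1e5, duration 34/12 y
  adult_pop <- 86 * 1000
  expect_equal(ps$prevalent_cases[ps$sex == "male"],
               2 / 1e5 * adult_pop * 34 / 12)
  # denominator is the full all-age population of the stratum
  expect_equal(ps$population[ps$sex == "male"], 101 * 1000)
  expect_equal(ps$prevalence_per_100k[ps$sex == "overall"],
               ps$prevalent_cases[ps$sex == "overall"] /
                 ps$population[ps$sex == "overall"] * 1e5)
  # linearity: doubling durations doubles prevalence exactly
  dur2 <- duration_table(c("<40" = 68, "40-79" = 68, "80+" = 68))
  ps2 <- project_prevalence(rt, proj, dur2)
  expect_equal(ps2$prevalent_cases, 2 * ps$prevalent_cases, tolerance = 1e-12)
  # linearity in rates
  ps3 <- project_prevalence(flat_rate_table(4), proj, dur)
  expect_equal(ps3$prevalent_cases, 2 * ps$prevalent_cases, tolerance = 1e-12)
  expect_error(project_prevalence(rt, proj, duration_table(
    c("<40" = 56, "40-79" = 35, "80+" = 26))[1:2, ]), "lacks cohort")
})

test_that("scenario multipliers follow their closed forms", {
  s <- als_scenarios()
  expect_equal(scenario_multiplier(s$s2, 34), 1.02)
  expect_equal(scenario_multiplier(s$s3, 34), 1.05)
  expect_equal(scenario_multiplier(s$s1, 34), 37 / 34)
  expect_equal(scenario_multiplier(s$s1, c(56, 35, 26)),
               c(59, 38, 29) / c(56, 35, 26))
  # f = 0 is a no-op for any transform
  none <- scenario_spec("none", 0, "multiply", amount = 3)
  expect_equal(scenario_multiplier(none, c(12, 34)), c(1, 1))
  expect_equal(scenario_multiplier(s$s4, 34, life_expectancy_months = 34),
               1)
  expect_error(scenario_multiplier(s$s3, 0), "positive")
  expect_error(scenario_spec("bad", 1.4, "multiply", 2), "\\[0, 1\\]")
})

test_that("multiplicative scenarios equal baseline times the closed form", {
  fx <- uk_fixture(1)
  yrs <- c(2020, 2050)
  base <- project_prevalence(fx$rates, fx$projection, fx$durations,
                             years = yrs)
  s3 <- apply_scenario(fx$rates, fx$projection, fx$durations,
                       als_scenarios()$s3, years = yrs)
  expect_equal(s3$prevalent_cases, base$prevalent_cases * 1.05,
               tolerance = 1e-12)
  expect_equal(s3$prevalence_per_100k, base$prevalence_per_100k * 1.05,
               tolerance = 1e-12)
  # microsimulation oracle: average duration over a simulated population
  # in which a random 10% subgroup survives 1.5x as long
  set.seed(99)
  n <- 1e5
  d <- rexp(n, log(2) / 34)
  affected <- runif(n) < 0.10
  ratio <- mean(d * ifelse(affected, 1.5, 1)) / mean(d)
  expect_equal(ratio, 1.05, tolerance = 0.005)
  # identity scenario returns the baseline series exactly
  id <- scenario_spec("id", 0, "multiply", amount = 1.5)
  same <- apply_scenario(fx$rates, fx$projection, fx$durations, id,
                         years = yrs)
  expect_equal(same$prevalent_cases, base$prevalent_cases, tolerance = 1e-12)
})

test_that("scenarios order as their affected fractions and gains dictate", {
  fx <- uk_fixture(3)
  s <- als_scenarios()
  yrs <- 2020
  val <- function(series) {
    series$prevalence_per_100k[series$sex == "overall"]
  }
  base <- val(project_prevalence(fx$rates, fx$projection, fx$durations,
                                 years = yrs))
  v2 <- val(apply_scenario(fx$rates, fx$projection, fx$durations, s$s2,
                           years = yrs))
  v3 <- val(apply_scenario(fx$rates, fx$projection, fx$durations, s$s3,
                           years = yrs))
  v4 <- val(apply_scenario(fx$rates, fx$projection, fx$durations, s$s4,
                           life = fx$life, years = yrs))
  expect_lt(base, v2)
  expect_lt(v2, v3)
  # synthetic life expectancy far exceeds 1.5x the disease median at every
  # band, so halting progression dominates the 50% gain
  expect_gt(v4, v3)
})

test_that("add-months scenarios support per-cohort and overall-median modes", {
  fx <- uk_fixture(1)
  s1 <- als_scenarios()$s1
  per <- apply_scenario(fx$rates, fx$projection, fx$durations, s1,
                        years = 2020)
  ov <- apply_scenario(fx$rates, fx$projection, fx$durations, s1,
                       years = 2020, scenario1_mode = "overall_median")
  base <- project_prevalence(fx$rates, fx$projection, fx$durations,
                             years = 2020)
  # overall-median mode is a uniform 37/34 scaling of the baseline
  expect_equal(ov$prevalent_cases, base$prevalent_cases * 37 / 34,
               tolerance = 1e-12)
  # per-cohort mode scales the younger cohorts less than 37/34 and the
  # oldest more
  expect_false(isTRUE(all.equal(per$prevalent_cases, ov$prevalent_cases)))
})

test_that("life-table scenario respects coverage and the year cap", {
  fx <- uk_fixture(1)
  s4 <- als_scenarios()$s4
  expect_error(apply_scenario(fx$rates, fx$projection, fx$durations, s4,
                              life = fx$life, years = c(2060, 2080)),
               "2066")
  expect_error(apply_scenario(fx$rates, fx$projection, fx$durations, s4,
                              years = 2020),
               "life table")
  # default years stop at the cap
  ps <- apply_scenario(fx$rates, fx$projection, fx$durations, s4,
                       life = fx$life)
  expect_equal(max(ps$year), 2066)
  expect_equal(min(ps$year), 2020)
})

test_that("life expectancy lookup converts years to months and refuses gaps", {
  life <- data.frame(year = 2030, sex = "female", age = 72,
                     expected_years = 10)
  expect_equal(life_expectancy_lookup(life, 72, "female", 2030), 120)
  expect_error(life_expectancy_lookup(life, 72, "female", 2070),
               "does not cover")
  expect_error(life_expectancy_lookup(life, 105, "female", 2030),
               "no entry")
})

test_that("calibrated national fixture reproduces its anchors and grows", {
  fx <- uk_fixture(1)
  base <- project_prevalence(fx$rates, fx$projection, fx$durations,
                             years = c(2020, 2066, 2116))
  ov <- base[base$sex == "overall", ]
  expect_equal(ov$prevalence_per_100k[ov$year == 2020], 8.58,
               tolerance = 1e-9)
  # aging population: prevalence and incidence rise over the horizon
  expect_lt(ov$prevalence_per_100k[ov$year == 2020],
            ov$prevalence_per_100k[ov$year == 2066])
  expect_lt(ov$prevalence_per_100k[ov$year == 2066],
            ov$prevalence_per_100k[ov$year == 2116])
  inc <- incidence_totals(project_incidence(fx$rates, fx$projection,
                                            years = c(2020, 2060, 2116)))
  ovi <- inc$cases[inc$sex == "overall"]
  expect_equal(ovi[1], 1701, tolerance = 1e-6)
  expect_true(all(diff(ovi) > 0))
})
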