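# Rate estimation: exact Poisson and Wilson intervals, crude and
# cell-specific rates, direct standardization, rate ratios, pooling,
# point prevalence.

test_that("exact Poisson limits match the frozen tail-sum oracle values", {
  ci <- poisson_exact_ci(10)
  expect_equal(ci[1, "low"], 4.795388696, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(ci[1, "high"], 18.390356042, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(poisson_exact_ci(0)[1, "low"], 0, ignore_attr = TRUE)
  expect_error(poisson_exact_ci(-1), "nonnegative")
  expect_error(poisson_exact_ci(3, level = 1.2), "level")
})

test_that("crude rates rescale counts and intervals by person-years", {
  expect_equal(crude_rate(20, 1e6)$rate, 2.0)
  r0 <- crude_rate(0, 1e6)
  expect_equal(r0$rate, 0)
  expect_equal(r0$ci_low, 0)
  r <- crude_rate(10, 5e5)
  expect_equal(r$rate, 2.0)
  expect_equal(r$ci_low, 4.795388696 / 5e5 * 1e5, tolerance = 1e-8)
  expect_equal(r$ci_high, 18.390356042 / 5e5 * 1e5, tolerance = 1e-8)
  expect_error(crude_rate(5, 0), "positive")
})

test_that("crude rate on the inner-city fixture echoes the printed interval", {
  # 122.9 weighted cases over 680,500 persons x 14 years
  r <- crude_rate(122.9, 680500 * 14)
  expect_equal(r$rate, 1.29, tolerance = 0.005)
  expect_equal(r$ci_low, 1.07, tolerance = 0.01)
  expect_equal(r$ci_high, 1.53, tolerance = 0.01)
})

test_that("cell-specific rates divide by cell person-years", {
  counts <- count_table(0)
  counts$count[counts$sex == "male" & counts$age_band == "65-69"] <- 7
  counts$count[counts$sex == "male" & counts$age_band == "70-74"] <- 0.5
  pop <- flat_population(25000)
  pop$count[pop$sex == "male" & pop$age_band == "70-74"] <- 50000
  rt <- specific_rates(counts, pop, 14)
  expect_s3_class(rt, "rate_table")
  expect_equal(rt$rate[rt$sex == "male" & rt$age_band == "65-69"],
               7 / (25000 * 14) * 1e5)
  expect_equal(rt$rate[rt$sex == "male" & rt$age_band == "70-74"],
               0.5 / (50000 * 14) * 1e5)
  # homogeneity: counts proportional to population give identical rates
  counts2 <- count_table(0)
  pop2 <- flat_population(10000)
  pop2$count <- seq(10000, 41000, 1000)
  counts2$count <- pop2$count * 2e-4
  rt2 <- specific_rates(counts2, pop2, 10)
  expect_true(all(abs(rt2$rate - rt2$rate[1]) < 1e-9))
  # zero denominators are named errors
  pop$count[3] <- 0
  expect_error(specific_rates(counts, pop, 14), "male 25-29")
})

test_that("direct standardization is a standard-weighted mean of band rates", {
  counts <- count_table(1)
  pop <- flat_population(1e5)
  rt <- specific_rates(counts, pop, 1)
  # constant cell rates: standardized rate equals that constant, any standard
  std <- flat_population(1)
  std$count <- seq_len(32) * 1000
  ds <- direct_standardize(rt, std)
  expect_equal(ds$overall$rate, rt$rate[1], tolerance = 1e-12)
  expect_equal(ds$male$rate, rt$rate[1], tolerance = 1e-12)
  # self-standardization identity: standard = study population
  counts2 <- count_table(abs(sin(1:32)) * 20 + 1)
  rt2 <- specific_rates(counts2, pop, 1)
  ds2 <- direct_standardize(rt2, pop)
  crude_overall <- sum(counts2$count) / sum(pop$count * 1) * 1e5
  expect_equal(ds2$overall$rate, crude_overall, tolerance = 1e-9)
  # two-band hand example: rates 1 and 3, weights 25%/75% -> 2.5
  expect_equal(sum(c(1, 3) * c(0.25, 0.75)), 2.5)
  ds_by_hand <- sum(rt2$rate * pop$count) / sum(pop$count)
  expect_equal(ds2$overall$rate, ds_by_hand)
  # bounded by the band-rate range
  expect_gte(ds2$overall$rate, min(rt2$rate))
  expect_lte(ds2$overall$rate, max(rt2$rate))
})

test_that("binomial-approximation SE scales as 1/sqrt(n)", {
  a <- standardized_rate_se(2.74, 62760000)
  b <- standardized_rate_se(2.74, 2 * 62760000)
  expect_equal(a$se / b$se, sqrt(2), tolerance = 1e-9)
  expect_equal(standardized_rate_se(0, 1000)$se, 0)
  # national-scale denominator reproduces the printed interval's shape
  expect_equal(a$ci_low, 2.59, tolerance = 0.03)
  expect_equal(a$ci_high, 2.88, tolerance = 0.03)
  expect_error(standardized_rate_se(2, 0), "positive")
})

test_that("standardized rate ratio uses a log-normal interval and reciprocates", {
  r1 <- rate_estimate(3.25, 3.09, 3.40, 0.95, "binomial_se")
  r2 <- rate_estimate(2.10, 1.97, 2.22, 0.95, "binomial_se")
  srr <- standardized_rate_ratio(r1, r2)
  expect_equal(srr$ratio, 3.25 / 2.10)
  expect_lt(srr$ci_low, srr$ratio)
  expect_gt(srr$ci_high, srr$ratio)
  expect_equal(standardized_rate_ratio(r1, r1)$ratio, 1)
  ab <- standardized_rate_ratio(r1, r2)$ratio
  ba <- standardized_rate_ratio(r2, r1)$ratio
  expect_equal(ab * ba, 1, tolerance = 1e-12)
  r0 <- rate_estimate(0, 0, 0.5, 0.95, "binomial_se")
  expect_error(standardized_rate_ratio(r1, r0), "positive")
})

test_that("pooling sums cells, re-substitutes, and sits between the regions", {
  counts_a <- count_table(0); counts_a$count <- rep(c(1, 0), 16)
  counts_b <- count_table(0); counts_b$count <- rep(c(3, 0), 16)
  pop <- flat_population(2e4)
  pooled <- pool_regions(counts_a, pop, counts_b, pop, 10)
  # equal populations: pooled cell rate is the mean of the regional rates
  ra <- specific_rates(substitute_zero_cells(counts_a), pop, 10)
  rb <- specific_rates(substitute_zero_cells(counts_b), pop, 10)
  cell <- pooled$sex == "male" & pooled$age_band == "15-19"
  expect_equal(pooled$rate[cell],
               mean(c(ra$rate[cell], rb$rate[cell])))
  # substitution happens after pooling: a cell empty in both regions gets
  # one 0.5, not two
  empty <- pooled$sex == "male" & pooled$age_band == "20-24"
  expect_equal(pooled$n_events[empty], 0.5)
  # pooled crude rate lies between the two regional crude rates
  crude <- function(rt) sum(rt$n_events) / sum(rt$person_years)
  expect_gte(crude(pooled), min(crude(ra), crude(rb)) - 1e-12)
  expect_lte(crude(pooled), max(crude(ra), crude(rb)) + 1e-12)
  expect_error(pool_regions(counts_a, pop, counts_b[1:10, ], pop, 10),
               "do not match")
})

test_that("Wilson interval matches its closed form and stays in [0, 1]", {
  ci <- wilson_ci(5, 100)
  expect_equal(ci[1, "low"], 0.021543679, tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(ci[1, "high"], 0.11175047, tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(wilson_ci(0, 100)[1, "low"], 0, ignore_attr = TRUE)
  for (k in c(0, 1, 17, 99, 100)) {
    ci <- wilson_ci(k, 100)
    expect_gte(ci[1, "low"], 0)
    expect_lte(ci[1, "high"], 1)
  }
  expect_error(wilson_ci(5, 0), "positive")
  expect_error(wilson_ci(11, 10), "\\[0, n\\]")
})

test_that("point prevalence rescales the Wilson interval per 100,000", {
  expect_equal(point_prevalence(0, 1e5)$rate, 0)
  p <- point_prevalence(44, 530000)
  expect_equal(p$rate, 8.30, tolerance = 0.005)   # 44 / 530,000 by hand
  expect_equal(p$method, "wilson")
  # scale invariance of the point estimate
  expect_equal(point_prevalence(88, 1060000)$rate, p$rate)
  expect_error(point_prevalence(5, 0), "positive")
})

test_that("one-band-per-sex standardization returns that band's rate exactly", {
  counts <- count_table(2)
  counts$count[counts$sex == "female" & counts$age_band == "60-64"] <- 7
  counts$count[counts$sex == "male" & counts$age_band == "60-64"] <- 3
  pop <- flat_population(5e4)
  rt <- specific_rates(counts, pop, 5)
  std <- flat_population(0)
  std$count[std$age_band == "60-64"] <- 1000
  ds <- direct_standardize(rt, std)
  expect_equal(ds$female$rate,
               rt$rate[rt$sex == "female" & rt$age_band == "60-64"])
  expect_equal(ds$male$rate,
               rt$rate[rt$sex == "male" & rt$age_band == "60-64"])
})
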