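---
title: "Estimating ALS incidence and projecting prevalence under treatment scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ALS incidence and projecting prevalence under treatment scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alsprev)
```

## The problem

Amyotrophic lateral sclerosis (ALS) is a rapidly fatal motor neuron
disease with an annual incidence around 2 per 100,000 person-years and a
median survival of roughly three years from symptom onset. Because
incidence rises steeply with age, an aging population will carry more
incident and prevalent cases even if age-specific risk never changes; and
any treatment that lengthens survival converts directly into higher
prevalence. `alsprev` implements that whole chain as testable pieces:

1. **Registry ingestion** — read clinic case records, apply explicit
   exclusion rules with an audit trail, weight cases by the fraction of
   their postcode sector inside the catchment, and cross-tabulate into a
   sex by 5-year age-band grid (15–19 … 85–89, 90+).
2. **Rates** — crude and age/sex-specific incidence per 100,000
   person-years with exact Poisson intervals, direct standardization to a
   reference population, standardized rate ratios between regions,
   pooling of regions, and Wilson-interval point prevalence.
3. **Survival** — a from-scratch Kaplan–Meier product-limit analysis of
   disease duration (onset to death or censoring, in months), overall and
   in three age cohorts (<40, 40–79, 80+).
4. **Projection** — apply the fitted rates to population projections year
   by year (2020–2116), convert incidence to prevalence through median
   duration, and rerun under hypothetical treatment scenarios.
5. **Synthetic data** — generators for registries, populations,
   projections and life tables with the statistical structure the
   estimators assume, so everything runs without confidential records.

## Statistical model and conventions

### Counting and weighting

Cases are grouped by sex and age at diagnosis into 5-year bands; ages 90
and over pool into an open band, and under-15s are rejected outright (the
band scheme starts at 15 because the disease is adult-onset; no pediatric
band exists). Postcode sectors straddle catchment boundaries, so each
incident case contributes its sector's overlap fraction rather than a
whole count; cell totals are therefore fractional. A cell with *exactly*
zero cases receives a substitute count of 0.5 so that projections never
extrapolate from an empty cell. Two conventions worth stating:

* A weighted cell total that is positive but below 0.5 (say 0.4) is left
  untouched — substitution targets empty cells only.
* When two regions are pooled, pooling happens on raw counts and the 0.5
  substitution is re-evaluated afterwards, because a cell empty in one
  region is often rescued by real cases from the other.

Exclusions run in a fixed order — non-MND diagnoses (lower motor neuron
syndrome, Kennedy's disease, other), then missing age at diagnosis, then
(for survival analyses only) missing onset date — so audit flowcharts are
reproducible. Records with a missing end event are treated as censored at
the end date, with a warning rather than silence.

### Intervals

Cell and crude rates use the exact Poisson interval, evaluated through
the chi-square identity `low = qchisq(a/2, 2k)/2`,
`high = qchisq(1-a/2, 2k+2)/2`, which extends smoothly to the fractional
counts produced by weighting and substitution. The test suite checks this
against an independent tail-sum bisection oracle at every integer count
up to 50 (6 significant figures). Exact intervals for discrete data are
conservative: their true coverage is at least the nominal level, and the
coverage test asserts exactly that (≥ 95% minus Monte-Carlo slack over
500 replicate registries) rather than a two-sided band that a correct
exact method would fail at small counts.

Directly standardized rates are standard-count weighted means of band
rates. Their interval treats the standardized rate as a binomial
proportion `p = rate/100000` observed on the standard population total:
`se = sqrt(p(1-p)/n)`. That is an *interpretation* — the binomial
approximation is conventional for standardized-rate intervals but the
precise formulation varies between texts — and we document it rather than
claim it matches any particular software. The standardized rate ratio
between two regions gets a log-normal interval via the delta method,
again a documented choice. Point prevalence uses the Wilson score
interval, rescaled per 100,000.

### Kaplan–Meier duration

Durations run from symptom onset to death or last follow-up, floored to
whole months (30.4375 days each, minimum one month) because reported
medians are integer months. The product-limit estimator is written from
scratch (risk sets count subjects at or beyond each distinct time, so
tied events and censorings resolve events-first); the `survival` package
appears only as an oracle in tests, where the two must agree to 1e-10 on
200 random tied, censored samples. The median is the first event time
where the curve reaches 0.5 (the ≤ convention, so a curve that touches
0.5 exactly yields that time); its interval inverts the pointwise
Greenwood band on the complementary log-log scale through the same
definition, and the reported standard error is the interval width over
twice the normal quantile. A curve that never reaches 0.5 yields a
flagged, undefined median — a legal result. The restricted mean is the
area under the curve up to the largest observed time by default, with the
usual Greenwood-based area variance. Age cohorts are assigned from age at
diagnosis (the one age consistently available): <40, 40–79 inclusive,
80+.

### Projection and scenarios

Incidence is assumed constant over the projection horizon: incident
cases in a cell-year are `rate/1e5 × population(year, sex, band)`.
Prevalent cases multiply that by the cohort's median duration in years
(bands 15–39 → <40, 40–79 → 40–79, 80+ → 80+); per-100,000 prevalence
divides each stratum's prevalent count by the same year's full projected
population of that stratum (all ages, both when sex-specific and
overall). Prevalence is therefore exactly linear in each cohort's
duration and each band's rate, which the tests exploit as machine-precision
scaling identities.

Four treatment scenarios transform durations for an affected fraction
`f` of patients:

* **s1** (new riluzole-equivalent): +3 months for everyone (`f = 1`).
* **s2** (*SOD1* gene therapy): duration ×1.5 for `f = 0.04`.
* **s3** (*C9orf72* gene therapy): duration ×1.5 for `f = 0.10`.
* **s4** (*C9orf72* progression halted): the affected 10% revert to
  period life expectancy for their age, sex and calendar year.

For multiplicative scenarios the population-average duration is the
closed form `1 - f + f·m` times baseline — identical in every cohort, so
the scenario series equals baseline times 1.02 (s2) or 1.05 (s3) to
machine precision; a per-case microsimulation in the tests confirms the
closed form within Monte-Carlo error. The additive scenario is
implemented per cohort by default (each cohort median gains 3 months); a
toggle applies the overall-median ratio (37/34) uniformly instead, since
published 2020-level worked values are consistent with overall-median
scaling while later-year values hint at per-cohort arithmetic — both
modes are exposed and only the arithmetic consistent with the worked
examples is pinned in tests. The life-table scenario resolves each band
to its representative age (band midpoint; 92 for 90+) and takes the
period life expectancy in the projection year itself — period life
expectancy is defined per calendar year and no cohort-interpolation rule
is imposed. Life tables stop at 2066, and lookups beyond coverage are
errors by design: the scenario is simply not evaluable there.

## The synthetic generator

The generator emulates the *structure* the estimators consume, not real
demography:

* **Registries.** Either a fixed total with planted exclusions
  (deterministic counts of non-MND diagnoses, missing onset, missing age
  in disjoint record sets — used for flowchart-fidelity fixtures) or
  per-cell Poisson counts from a configured rate surface (used for
  coverage and parameter-recovery properties). Survival is exponential
  within cohort with medians 56 / 35 / 26 months (the one-parameter
  model a set of target medians fully determines); censoring is
  administrative at a fixed follow-up cut-off, matching how registers
  censor at last recorded follow-up, and leaves roughly 10–20% of
  recent-onset cases censored. Ages are truncated-normal around the
  late-60s peak; the default rate surface rises to a peak in the 70s–80s
  with a male:female ratio near 1.17 and 90+ rates of 7.56 (male) and
  1.99 (female) per 100,000.
* **Region presets.** `lsl` — 152 raw cases, one LMN exclusion, and three
  sectors with fractions 1.0/0.5/0.4 holding 96/49/6 kept cases, so the
  weighted count is exactly 122.9 over a 15+ population of 680,500
  (crude rate 1.29 per 100,000 over 14 years). `canterbury` — 269 raw
  cases, 1 LMN + 2 Kennedy's + 2 missing-age, leaving 264. `seals` — 953
  raw cases, 6 non-MND + 43 missing-onset + 2 missing-age, leaving 902
  for survival. These denominators and plants were chosen once so that
  the synthetic fixtures echo the reported counts and rates.
* **Populations and projections.** A plateau-then-exponential age
  pyramid, projected with annual growth concentrated in the 80+ and 90+
  groups so old-age cohorts grow severalfold over a century.
* **Life tables.** Expected remaining years decline linearly in age to
  sex-specific floors, sit lower for males, improve mildly by calendar
  year, and cover 2020–2066 only.
* **The calibrated national fixture** (`uk_fixture()`) anchors two
  scales once: the rate surface is scaled so baseline 2020 overall
  prevalence is exactly 8.58 per 100,000, then the projection is scaled
  so 2020 incident cases total 1,701. Population scaling leaves
  per-100,000 prevalence invariant, so the two calibrations coexist.

What passing tests on synthetic data do *not* show: the generator makes
no attempt to reproduce real UK demography, migration, ethnicity
structure, or register ascertainment gaps, and the exponential survival
model has a constant hazard that real ALS cohorts violate (hazard falls
with time from onset among survivors). Results on real registries depend
on those features; the tests certify the estimators, not the world.

## Worked example

```{r example}
reg <- gen_registry(preset_config("canterbury", seed = 1))
excl <- apply_exclusions(reg$cases, "incidence")
excl$n_kept          # 264 kept of 269
excl$audit

counts <- substitute_zero_cells(bin_cases(weight_by_sector(excl$kept, reg$overlaps)))
pop <- gen_population(preset_config("canterbury", seed = 1))$baseline
rates <- specific_rates(counts, pop, study_years = 14)
crude_rate(sum(counts$count), 522400 * 14)

fx <- uk_fixture(seed = 1)
project_prevalence(fx$rates, fx$projection, fx$durations, years = 2020)
apply_scenario(fx$rates, fx$projection, fx$durations,
               als_scenarios()$s3, years = 2020)
```

## Problem sizes and numerical choices

The package's own test and example runs use the preset registry sizes
(152/269/953 cases), 500 replicate registries for the coverage property,
200 random samples for the product-limit oracle comparison, 10 seeds of
n = 900 for exponential median recovery, and short year subsets of the
97-year projection horizon where a full sweep adds nothing — the
projection is linear in rates and durations, so a few anchor years
exercise every code path. Ties in the product-limit risk sets resolve
events-first; the median uses the ≤ 0.5 convention; reported tables round
half-up to 2 decimals at presentation only, never inside estimation.

## Known limitations

* Constant incidence over a century is an assumption made visible, not a
  finding; the projection has no uncertainty propagation (point
  projections only).
* The binomial-approximation interval for standardized rates and the
  log-normal SRR interval are documented interpretations; median standard
  errors depend on the chosen interval inversion and are not claimed
  identical to any particular software's formula.
* No record linkage, capture–recapture correction, geocoding, indirect
  standardization, or Cox/parametric survival modelling — those are
  outside the package's scope.
* Prevalence counting at a point date uses whole persons (sector
  weighting applies to the incidence path only; configurable upstream by
  weighting before counting if a weighted variant is wanted).
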