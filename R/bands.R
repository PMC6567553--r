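# Age-band scheme: 5-year bands from 15-19 up to 85-89, open-ended 90+.
# Adult-onset disease; ages below 15 are outside the scheme and rejected.

.sexes <- c("male", "female")

#' Age bands used throughout the package
#'
#' Sixteen 5-year age bands from 15-19 to 85-89 plus the open-ended band
#' `90+`, in ascending order. Every count, population and rate table is
#' indexed by these bands crossed with sex.
#'
#' @return Character vector of band labels, length 16.
#' @export
#' @examples
#' als_age_bands()
als_age_bands <- function() {
  c(paste(seq(15, 85, 5), seq(19, 89, 5), sep = "-"), "90+")
}

#' Assign ages to 5-year bands
#'
#' @param age Numeric vector of ages in years. `NA` passes through as `NA`.
#' @return Character vector of band labels; ages of 90 and above pool into
#'   the open `90+` band.
#' @export
#' @examples
#' age_to_band(c(15, 67, 89, 104))
age_to_band <- function(age) {
  bad <- which(!is.na(age) & age < 15)
  if (length(bad)) {
    stop("age below 15 is outside the band scheme (positions ",
         paste(bad, collapse = ", "), ")")
  }
  idx <- findInterval(age, seq(15, 90, 5))
  out <- als_age_bands()[pmin(idx, 16L)]
  out[is.na(age)] <- NA_character_
  out
}

band_lower_age <- function(band) {
  as.numeric(sub("[-+].*$|\\+$", "", band))
}

#' Representative (midpoint) age of a band
#'
#' Used when a single age must stand for a whole band, e.g. when looking up
#' period life expectancy. The open `90+` band is represented by age 92.
#'
#' @param band Character vector of band labels from [als_age_bands()].
#' @return Numeric vector of representative ages.
#' @export
band_midpoint <- function(band) {
  ifelse(band == "90+", 92, band_lower_age(band) + 2)
}

#' Map age bands onto the three survival cohorts
#'
#' Disease-duration estimates are made for three age cohorts: under 40,
#' 40-79, and 80 and over. Bands 15-39 map to `<40`, bands 40-79 to
#' `40-79`, and 80+ bands to `80+`.
#'
#' @param band Character vector of band labels.
#' @return Character vector of cohort labels.
#' @export
band_to_cohort <- function(band) {
  lo <- band_lower_age(band)
  ifelse(lo < 40, "<40", ifelse(lo < 80, "40-79", "80+"))
}

#' Survival cohort of an age
#'
#' @param age Numeric vector of ages in years.
#' @return Character vector: `<40` for age < 40, `40-79` for 40-79
#'   inclusive, `80+` for 80 and over.
#' @export
cohort_of_age <- function(age) {
  ifelse(age < 40, "<40", ifelse(age < 80, "40-79", "80+"))
}

duration_cohorts <- function() c("<40", "40-79", "80+")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Presentation rounding for reported tables: exact halves round up (9.005
#' becomes 9.01), unlike base R's round-half-to-even. Applied only when
#' formatting results, never inside estimation.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
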