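# Shared helpers: an independent exact-Poisson oracle (tail-sum bisection,
# no chi-square), and small registry builders used across test files.

# For integer k: lower limit solves P(X >= k; mu) = (1 - level)/2, upper
# solves P(X <= k; mu) = (1 - level)/2, each found by root-finding on the
# cumulative Poisson tail.
poisson_tail_oracle <- function(k, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (k == 0) 0 else {
    stats::uniroot(function(m) 1 - stats::ppois(k - 1, m) - a,
                   c(1e-9, 5 * k + 20), tol = 1e-12)$root
  }
  hi <- stats::uniroot(function(m) stats::ppois(k, m) - a,
                       c(1e-9, 5 * k + 60), tol = 1e-12)$root
  c(low = lo, high = hi)
}

# Minimal well-formed registry rows; override any field per record.
mk_cases <- function(n = 3, ...) {
  base <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    sex = rep(c("male", "female"), length.out = n),
    date_of_onset = "2010-01-15",
    date_of_diagnosis = "2010-06-15",
    age_at_diagnosis = "65",
    end_date = "2013-06-15",
    end_event = "died",
    diagnosis = "ALS",
    el_escorial = "probable",
    sector_id = "S1",
    stringsAsFactors = FALSE
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

write_cases_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

flat_population <- function(count = 25000) {
  tab <- count_table(count)
  names(tab)[names(tab) == "count"] <- "count"
  tab[, c("sex", "age_band", "count")]
}
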