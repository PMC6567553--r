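# Registry ingestion: read case files, validate, apply the exclusion rules,
# weight by postcode-sector catchment overlap, and cross-tabulate into the
# sex x age-band count grid that the rate estimators consume.

.diagnoses <- c("ALS", "PLS", "PMA", "pseudobulbar_palsy",
                "kennedys", "LMN_syndrome", "other")
.el_escorial <- c("definite", "probable", "probable_lab", "possible",
                  "suspected", "missing")
.non_mnd <- c("LMN_syndrome", "kennedys", "other")

#' Read a case-registry CSV
#'
#' Expects one row per patient with columns `patient_id`, `sex`,
#' `date_of_onset`, `date_of_diagnosis`, `age_at_diagnosis`, `end_date`,
#' `end_event`, `diagnosis`, `el_escorial`, `sector_id`; dates in ISO-8601.
#' Missing values are preserved as `NA` (a blank `el_escorial` is recoded to
#' the explicit level `"missing"`); nothing is imputed. Records violating
#' the date invariant (`end_date` before `date_of_onset`) or carrying
#' unknown sex/diagnosis codes raise an error naming the offending rows.
#' Records with a blank `end_event` are treated as censored at `end_date`,
#' with a warning.
#'
#' @param path Path to the CSV file.
#' @return A data frame of class `case_records`, one row per registry entry.
#' @export
load_cases <- function(path) {
  if (!file.exists(path)) stop("cannot read case registry file: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"), strip.white = TRUE)
  req <- c("patient_id", "sex", "date_of_onset", "date_of_diagnosis",
           "age_at_diagnosis", "end_date", "end_event", "diagnosis",
           "el_escorial", "sector_id")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop("registry file lacks column(s): ",
                         paste(miss, collapse = ", "))
  validate_cases(raw)
}

#' Validate raw case records
#'
#' Applies the field-level checks described in [load_cases()] to an
#' already-loaded character data frame and returns typed `case_records`.
#'
#' @param raw Data frame with the registry columns as character vectors.
#' @return A data frame of class `case_records`.
#' @export
validate_cases <- function(raw) {
  for (col in names(raw)) {
    if (is.character(raw[[col]])) {
      blank <- !is.na(raw[[col]]) & raw[[col]] == ""
      raw[[col]][blank] <- NA
    }
  }
  rows <- function(i) paste(i, collapse = ", ")
  parse_date <- function(x, col) {
    d <- as.Date(x, format = "%Y-%m-%d")
    bad <- which(!is.na(x) & is.na(d))
    if (length(bad)) stop("malformed ", col, " at row(s) ", rows(bad))
    d
  }
  bad <- which(!is.na(raw$sex) & !raw$sex %in% .sexes)
  if (length(bad)) stop("unknown sex code at row(s) ", rows(bad))
  bad <- which(!is.na(raw$diagnosis) & !raw$diagnosis %in% .diagnoses)
  if (length(bad)) stop("unknown diagnosis code at row(s) ", rows(bad))
  el <- raw$el_escorial
  el[is.na(el)] <- "missing"
  bad <- which(!el %in% .el_escorial)
  if (length(bad)) stop("unknown El Escorial category at row(s) ", rows(bad))

  onset <- parse_date(raw$date_of_onset, "date_of_onset")
  dx <- parse_date(raw$date_of_diagnosis, "date_of_diagnosis")
  end <- parse_date(raw$end_date, "end_date")
  age <- suppressWarnings(as.numeric(raw$age_at_diagnosis))
  bad <- which(!is.na(raw$age_at_diagnosis) & is.na(age))
  if (length(bad)) stop("malformed age_at_diagnosis at row(s) ", rows(bad))
  bad <- which(!is.na(age) & age < 0)
  if (length(bad)) stop("negative age_at_diagnosis at row(s) ", rows(bad))
  bad <- which(!is.na(end) & !is.na(onset) & end < onset)
  if (length(bad)) stop("end_date precedes date_of_onset at row(s) ", rows(bad))

  ev <- raw$end_event
  noev <- which(is.na(ev))
  if (length(noev)) {
    warning("end_event missing at row(s) ", rows(noev),
            "; treating as censored at end_date")
    ev[noev] <- "censored"
  }
  bad <- which(!ev %in% c("died", "censored"))
  if (length(bad)) stop("unknown end_event at row(s) ", rows(bad))

  out <- data.frame(
    patient_id = raw$patient_id, sex = raw$sex,
    date_of_onset = onset, date_of_diagnosis = dx,
    age_at_diagnosis = age, end_date = end, end_event = ev,
    diagnosis = raw$diagnosis, el_escorial = el,
    sector_id = raw$sector_id, stringsAsFactors = FALSE
  )
  class(out) <- c("case_records", "data.frame")
  out
}

#' Apply the registry exclusion rules
#'
#' For incidence analyses, records with a non-MND diagnosis (lower motor
#' neuron syndrome, Kennedy's disease, other) and records with no age at
#' diagnosis are dropped; every El Escorial certainty category, including
#' "suspected" and missing, is retained. Survival analyses additionally
#' drop records with no date of onset. Rules are applied in a fixed order
#' (diagnosis, then missing age, then missing onset) and each rule's tally
#' is recorded so the audit mirrors a sample-selection flowchart.
#'
#' @param cases A `case_records` data frame.
#' @param purpose `"incidence"` or `"survival"`.
#' @return A list with elements `kept` (the retained `case_records`),
#'   `audit` (data frame of `rule`, `n_excluded` in application order),
#'   `n_input`, and `n_kept`.
#' @export
apply_exclusions <- function(cases, purpose = c("incidence", "survival")) {
  purpose <- match.arg(purpose)
  rules <- list(
    LMN_syndrome      = function(df) df$diagnosis %in% "LMN_syndrome",
    kennedys          = function(df) df$diagnosis %in% "kennedys",
    other_diagnosis   = function(df) df$diagnosis %in% "other",
    missing_age_at_diagnosis = function(df) is.na(df$age_at_diagnosis)
  )
  if (purpose == "survival") {
    rules$missing_date_of_onset <- function(df) is.na(df$date_of_onset)
  }
  n_input <- nrow(cases)
  kept <- cases
  audit <- data.frame(rule = names(rules), n_excluded = 0L,
                      stringsAsFactors = FALSE)
  for (i in seq_along(rules)) {
    drop <- rules[[i]](kept)
    audit$n_excluded[i] <- sum(drop)
    kept <- kept[!drop, , drop = FALSE]
  }
  class(kept) <- class(cases)
  list(kept = kept, audit = audit, n_input = n_input, n_kept = nrow(kept))
}

#' Weight cases by postcode-sector catchment overlap
#'
#' Each incident case is weighted by the fraction of its postcode sector
#' lying inside the study catchment, so that sectors straddling the
#' catchment boundary contribute partial counts.
#'
#' @param cases A `case_records` data frame.
#' @param overlaps Data frame with columns `sector_id` and
#'   `fraction_in_catchment` (each in `[0, 1]`).
#' @param default_weight Weight for sectors absent from `overlaps`; when
#'   `NULL` (default) an unknown sector is an error naming the sector.
#' @return `cases` with an added numeric `weight` column.
#' @export
weight_by_sector <- function(cases, overlaps, default_weight = NULL) {
  if (!all(c("sector_id", "fraction_in_catchment") %in% names(overlaps))) {
    stop("overlaps must have columns sector_id and fraction_in_catchment")
  }
  f <- overlaps$fraction_in_catchment
  if (any(is.na(f)) || any(f < 0 | f > 1)) {
    stop("fraction_in_catchment must lie in [0, 1]")
  }
  idx <- match(cases$sector_id, overlaps$sector_id)
  if (anyNA(idx)) {
    unknown <- unique(cases$sector_id[is.na(idx)])
    if (is.null(default_weight)) {
      stop("no catchment fraction for sector(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  w <- f[idx]
  w[is.na(idx)] <- default_weight %||% NA_real_
  cases$weight <- w
  cases
}

#' Empty sex x age-band count grid
#'
#' @param counts Initial cell counts, recycled over the 32-cell grid
#'   (16 bands by 2 sexes).
#' @return Data frame of class `count_table` with columns `sex`,
#'   `age_band`, `count`, in fixed sex-major band order.
#' @export
count_table <- function(counts = 0) {
  grid <- expand.grid(age_band = als_age_bands(), sex = .sexes,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)[, c("sex", "age_band")]
  grid$count <- rep_len(counts, nrow(grid))
  rownames(grid) <- NULL
  class(grid) <- c("count_table", "data.frame")
  grid
}

#' Cross-tabulate weighted cases into the count grid
#'
#' Sums case weights into (sex, age band) cells; ages of 90 and above pool
#' into the open `90+` band. Every case must carry sex and age at
#' diagnosis (apply the exclusion rules first); ages below 15 are outside
#' the band scheme and raise an error.
#'
#' @param cases A `case_records` data frame.
#' @param weights Optional numeric weights; defaults to the `weight`
#'   column added by [weight_by_sector()], or 1 per case if absent.
#' @return A `count_table` whose total equals the sum of the weights.
#' @export
bin_cases <- function(cases, weights = NULL) {
  w <- weights %||% cases$weight %||% rep(1, nrow(cases))
  if (length(w) != nrow(cases)) stop("weights length must match cases")
  if (anyNA(cases$sex) || anyNA(cases$age_at_diagnosis)) {
    stop("all cases must carry sex and age_at_diagnosis; ",
         "apply_exclusions() first")
  }
  band <- age_to_band(cases$age_at_diagnosis)
  tab <- count_table()
  key <- paste(tab$sex, tab$age_band)
  sums <- tapply(w, paste(cases$sex, band), sum)
  hit <- match(names(sums), key)
  tab$count[hit] <- as.numeric(sums)
  tab
}

#' Substitute 0.5 into empty cells
#'
#' Cells whose count is exactly zero receive 0.5 so that downstream rate
#' extrapolation never multiplies from an empty cell; nonzero cells,
#' including fractional weighted counts below 0.5, are untouched. The
#' substitution is flagged per cell in a logical `substituted` column.
#'
#' @param table A `count_table`.
#' @return The table with zeros replaced by 0.5 and the flag column added.
#' @export
substitute_zero_cells <- function(table) {
  table$substituted <- table$count == 0
  table$count[table$substituted] <- 0.5
  attr(table, "zero_substituted") <- TRUE
  table
}

#' Count prevalent cases at a point date
#'
#' A case is prevalent on `at_date` if diagnosed on or before that date
#' (and on or after `window_start`, by default 1 January 1994) and still
#' alive on it: either death occurred after `at_date`, or follow-up was
#' censored on or after it.
#'
#' @param cases A `case_records` data frame.
#' @param at_date Prevalence date (`Date` or ISO-8601 string).
#' @param window_start Earliest qualifying diagnosis date.
#' @return Integer count of prevalent cases.
#' @export
count_prevalent <- function(cases, at_date, window_start = "1994-01-01") {
  at_date <- as.Date(at_date)
  window_start <- as.Date(window_start)
  dx <- cases$date_of_diagnosis
  alive <- ifelse(cases$end_event == "died",
                  cases$end_date > at_date,
                  cases$end_date >= at_date)
  sum(!is.na(dx) & dx >= window_start & dx <= at_date & alive, na.rm = TRUE)
}

#' Write an exclusion audit to disk
#'
#' @param audit The list returned by [apply_exclusions()].
#' @param path Output path for a small CSV mirroring the flowchart.
#' @return `path`, invisibly.
#' @export
write_audit <- function(audit, path) {
  df <- rbind(
    data.frame(rule = "input", n_excluded = NA_integer_,
               n_remaining = audit$n_input),
    cbind(audit$audit,
          n_remaining = audit$n_input - cumsum(audit$audit$n_excluded))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
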