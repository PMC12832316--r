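#' Deduplicate safety reports by case identifier
#'
#' A spontaneous-report case (`caseid`) accumulates versions (`primaryid`)
#' as follow-ups arrive.  Analyses retain the most recent version per case:
#' the one with the latest report date, ties broken by the greatest
#' `primaryid` (numeric comparison when all ids parse as numbers, lexical
#' otherwise).  The result is deterministic for any input ordering.
#'
#' @param cases case tibble from [faers_assemble()].
#' @return the retained cases, one per `caseid`, in (caseid-sorted)
#'   deterministic order, with attribute `cleaning_report`: a list with
#'   `input_cases`, `duplicates_removed`, `output_cases`.
#' @seealso [cleaning_report()]
#' @export
faers_dedup <- function(cases) {
  n_in <- nrow(cases)
  if (n_in == 0) {
    out <- cases
  } else {
    pid_num <- suppressWarnings(as.numeric(cases$primaryid))
    pid_key <- if (anyNA(pid_num)) xtfrm(cases$primaryid) else pid_num
    date_key <- as.numeric(cases$report_date)
    date_key[is.na(date_key)] <- -Inf   # undated versions lose to dated ones
    ord <- order(cases$caseid, -date_key, -pid_key)
    out <- cases[ord, , drop = FALSE]
    out <- out[!duplicated(out$caseid), , drop = FALSE]
  }
  rep <- list(
    input_cases = n_in,
    duplicates_removed = n_in - nrow(out),
    values_recoded = attr(cases, "cleaning_report")$values_recoded,
    output_cases = nrow(out)
  )
  attr(out, "cleaning_report") <- rep
  out
}

#' Retrieve the cleaning report attached to a case tibble
#'
#' @param cases tibble returned by [faers_dedup()] or
#'   [faers_recode_implausible()].
#' @return list with counts of inputs, removed duplicates and recoded
#'   values, or `NULL` if none is attached.
#' @export
cleaning_report <- function(cases) {
  attr(cases, "cleaning_report")
}

#' Read a drug synonym map
#'
#' Two-column delimited file mapping trade names, salt forms and common
#' misspellings to a canonical active-substance name.  Matching is
#' case-insensitive after trimming; synonym sets of different canonical
#' names must be disjoint.
#'
#' @param path path to a delimited file with columns `canonical`, `synonym`.
#' @param delim delimiter (default tab).
#' @return tibble with columns `canonical`, `synonym` (both normalised to
#'   lower case).
#' @export
read_synonym_map <- function(path, delim = "\t") {
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  if (!all(c("canonical", "synonym") %in% names(tbl))) {
    pv_validation_error("synonym map must have columns 'canonical' and 'synonym'")
  }
  synonym_map(tbl$canonical, tbl$synonym)
}

#' Build a drug synonym map in memory
#'
#' @param canonical,synonym equal-length character vectors.
#' @return normalised synonym map tibble (see [read_synonym_map()]).
#' @export
synonym_map <- function(canonical, synonym) {
  tbl <- tibble(
    canonical = str_squish_lower(canonical),
    synonym = str_squish_lower(synonym)
  ) |>
    distinct()
  # each canonical name is implicitly its own synonym
  tbl <- bind_rows(tbl, tibble(canonical = unique(tbl$canonical),
                               synonym = unique(tbl$canonical))) |>
    distinct()
  clash <- tbl |>
    distinct(.data$canonical, .data$synonym) |>
    count(.data$synonym) |>
    filter(.data$n > 1)
  if (nrow(clash) > 0) {
    pv_validation_error(paste0(
      "synonym(s) mapped to more than one canonical name: ",
      paste(clash$synonym, collapse = ", ")
    ))
  }
  tbl
}

#' Standardize raw drug names against a synonym map
#'
#' Exact lookup after trimming, whitespace squeezing and case folding;
#' names absent from the map return `NA` (the unmatched marker) — never a
#' fuzzy guess, so case selection stays auditable.
#'
#' @param raw_names character vector of reported drug names.
#' @param map synonym map from [synonym_map()] / [read_synonym_map()].
#' @return character vector of canonical names, `NA` where unmatched.
#' @export
#' @examples
#' m <- synonym_map(c("baricitinib", "tofacitinib"), c("olumiant", "xeljanz"))
#' drug_standardize(c("OLUMIANT", "  Xeljanz ", "aspirin"), m)
drug_standardize <- function(raw_names, map) {
  key <- str_squish_lower(raw_names)
  map$canonical[match(key, map$synonym)]
}

#' Standardize the drug names of every case
#'
#' Adds a `drug_canonical` list-column parallel to `drug_names`.
#'
#' @param cases case tibble.
#' @param map synonym map.
#' @return `cases` with the extra list-column.
#' @export
faers_standardize_drugs <- function(cases, map) {
  lens <- lengths(cases$drug_names)
  flat <- unlist(cases$drug_names, use.names = FALSE)
  canon <- drug_standardize(flat, map)
  cases$drug_canonical <- vctrs::vec_chop(canon,
                                          sizes = lens)
  cases
}

#' Recode implausible values as missing
#'
#' Negative onset intervals, ages outside a plausible human range and
#' weights outside a plausible range are data errors in spontaneous
#' reports (unit mix-ups, typos); they are recoded to missing and counted.
#' No other value is ever altered.
#'
#' @param cases case tibble.
#' @param age_range plausible age range in years (default `c(0, 120)`).
#' @param weight_range plausible weight range in kg (default `c(2, 400)`).
#' @return `cases` with recoded values and attribute `cleaning_report`
#'   carrying `values_recoded`, a named integer vector by field.
#' @export
faers_recode_implausible <- function(cases, age_range = c(0, 120),
                                     weight_range = c(2, 400)) {
  bad_onset <- !is.na(cases$onset_days) & cases$onset_days < 0
  bad_age <- !is.na(cases$age_years) &
    (cases$age_years < age_range[1] | cases$age_years > age_range[2])
  bad_wt <- !is.na(cases$weight_kg) &
    (cases$weight_kg < weight_range[1] | cases$weight_kg > weight_range[2])
  cases$onset_days[bad_onset] <- NA_integer_
  cases$age_years[bad_age] <- NA_real_
  cases$weight_kg[bad_wt] <- NA_real_
  rep <- attr(cases, "cleaning_report") %||% list()
  rep$values_recoded <- c(onset_days = sum(bad_onset), age_years = sum(bad_age),
                          weight_kg = sum(bad_wt))
  attr(cases, "cleaning_report") <- rep
  cases
}

#' Convert reported age to years
#'
#' FAERS demographics report age with a unit code.  Conversion factors:
#' decades x10, months /12, weeks /52.1775, days /365.25, hours /8766.
#'
#' @param value numeric age values (non-negative).
#' @param unit_code character codes among `YR`, `DEC`, `MON`, `WK`, `DY`,
#'   `HR`; empty strings yield `NA` silently, unknown codes yield `NA` with
#'   a warning.
#' @return age in years.
#' @export
#' @examples
#' age_harmonize(c(42, 24, 365.25), c("YR", "MON", "DY"))
age_harmonize <- function(value, unit_code) {
  factors <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.1775,
               DY = 1 / 365.25, HR = 1 / 8766)
  unit_code <- toupper(trimws(unit_code))
  f <- factors[unit_code]
  unknown <- !is.na(value) & is.na(f) & unit_code != ""
  if (any(unknown)) {
    warn(paste0("unknown age unit code(s): ",
                paste(unique(unit_code[unknown]), collapse = ", "),
                "; recoded as missing"))
  }
  unname(value * f)
}
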