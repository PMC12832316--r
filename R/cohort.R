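#' Select a drug/indication analysis cohort
#'
#' Retains reports where the study drug appears as a suspect drug (primary
#' or secondary role) with a qualifying therapeutic indication attached to
#' that same drug entry.  Optionally drops pediatric reports (age < 18);
#' reports with missing age are retained, because spontaneous-report
#' databases have large missing-age fractions and dropping them would bias
#' the cohort.
#'
#' @param cases cleaned, deduplicated case tibble with a `drug_canonical`
#'   list-column (see [faers_standardize_drugs()]).
#' @param drug canonical drug name.
#' @param indication_terms character vector of qualifying indication
#'   preferred terms (case-insensitive match after trimming); must be
#'   non-empty.
#' @param adult_only drop reports with known age < 18 years.
#' @return order-preserving subset of `cases`.
#' @export
select_cohort <- function(cases, drug,
                          indication_terms = "Alopecia areata",
                          adult_only = FALSE) {
  if (length(indication_terms) == 0) {
    pv_validation_error("`indication_terms` must contain at least one term")
  }
  if (!"drug_canonical" %in% names(cases)) {
    pv_validation_error(
      "`cases` lacks a drug_canonical column; run faers_standardize_drugs() first"
    )
  }
  terms <- str_squish_lower(indication_terms)
  lens <- lengths(cases$drug_canonical)
  flat <- tibble(
    row = rep(seq_len(nrow(cases)), lens),
    canonical = unlist(cases$drug_canonical, use.names = FALSE),
    role = unlist(cases$drug_roles, use.names = FALSE),
    indication = str_squish_lower(unlist(cases$drug_indications,
                                         use.names = FALSE))
  )
  hit <- flat$row[!is.na(flat$canonical) &
                    flat$canonical == str_squish_lower(drug) &
                    flat$role %in% c("PS", "SS") &
                    !is.na(flat$indication) &
                    flat$indication %in% terms]
  out <- cases[sort(unique(hit)), , drop = FALSE]
  if (adult_only) {
    out <- out[is.na(out$age_years) | out$age_years >= 18, , drop = FALSE]
  }
  out
}

#' Read a preferred-term to system-organ-class dictionary
#'
#' Stand-in for a licensed MedDRA PT->SOC table: a delimited file with
#' columns `pt` and `soc`, and an optional leading comment line
#' `# version: <label>`.
#'
#' @param path file path.
#' @param delim delimiter (default tab).
#' @return a `meddra_dict`: tibble (pt, soc) with attribute `version`.
#' @export
read_meddra_dict <- function(path, delim = "\t") {
  first <- readLines(path, n = 1)
  version <- if (grepl("^#\\s*version:", first)) {
    trimws(sub("^#\\s*version:", "", first))
  } else {
    "unversioned"
  }
  tbl <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  meddra_dict(tbl$pt, tbl$soc, version = version)
}

#' Build a PT -> SOC dictionary in memory
#'
#' @param pt,soc equal-length character vectors; each preferred term must
#'   map to exactly one system organ class.
#' @param version version label.
#' @return a `meddra_dict` tibble.
#' @export
meddra_dict <- function(pt, soc, version = "synthetic") {
  tbl <- distinct(tibble(pt = pt, soc = soc))
  if (anyDuplicated(tbl$pt)) {
    dup <- unique(tbl$pt[duplicated(tbl$pt)])
    pv_validation_error(paste0(
      "preferred term(s) mapped to more than one SOC: ",
      paste(head(dup, 5), collapse = ", ")
    ))
  }
  attr(tbl, "version") <- version
  class(tbl) <- c("meddra_dict", class(tbl))
  tbl
}

#' Write a PT -> SOC dictionary
#'
#' @param dict a `meddra_dict`.
#' @param path output path.
#' @param delim delimiter.
#' @return `path`, invisibly.
#' @export
write_meddra_dict <- function(dict, path, delim = "\t") {
  writeLines(paste0("# version: ", attr(dict, "version") %||% "unversioned"),
             path)
  readr::write_delim(as_tibble(dict), path, delim = delim, append = TRUE,
                     col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Expand a cohort to event-level records
#'
#' One record per (report, distinct preferred term) pair: repeats of the
#' same term within a report collapse to one record, so follow-up merges
#' cannot double-count events.  Every term must be covered by the
#' dictionary.
#'
#' @param cohort case tibble.
#' @param dict a `meddra_dict`.
#' @return tibble with columns `primaryid`, `pt`, `soc`.
#' @export
expand_events <- function(cohort, dict) {
  flat <- flatten_listcol(cohort$primaryid, cohort$events, "pt") |>
    distinct(.data$primaryid, .data$pt)
  miss <- setdiff(unique(flat$pt), dict$pt)
  if (length(miss) > 0) {
    pv_data_error(paste0(
      "preferred term(s) missing from the dictionary: ",
      paste(head(miss, 10), collapse = ", "),
      if (length(miss) > 10) paste0(" (and ", length(miss) - 10, " more)") else ""
    ))
  }
  flat$soc <- dict$soc[match(flat$pt, dict$pt)]
  flat
}

#' Assign the analysis age band
#'
#' @param age_years numeric vector (years), `NA` allowed.
#' @return factor with levels `under18`, `18_44`, `45_64`, `65_plus`,
#'   `not_specified`; missing age maps to `not_specified`.
#' @export
#' @examples
#' age_band(c(44.9, 45, 65, 17, NA))
age_band <- function(age_years) {
  lv <- c("under18", "18_44", "45_64", "65_plus", "not_specified")
  out <- rep("not_specified", length(age_years))
  out[!is.na(age_years) & age_years < 18] <- "under18"
  out[!is.na(age_years) & age_years >= 18 & age_years < 45] <- "18_44"
  out[!is.na(age_years) & age_years >= 45 & age_years < 65] <- "45_64"
  out[!is.na(age_years) & age_years >= 65] <- "65_plus"
  factor(out, levels = lv)
}

#' Days from therapy start to event onset
#'
#' @param therapy_start,event_date `Date` vectors.
#' @return integer days; `NA` when either endpoint is missing.  Negative
#'   intervals are data errors and are recoded by
#'   [faers_recode_implausible()], not here.
#' @export
compute_onset_days <- function(therapy_start, event_date) {
  as.integer(round(as.numeric(difftime(event_date, therapy_start,
                                       units = "days"))))
}

#' Assign the time-to-onset band
#'
#' Closed bands as printed in descriptive safety tables: 0-30, 31-60,
#' 61-90, 91-120, 121-150, 151-180, 181-360 days, then `over_360`.
#'
#' @param days integer onset days (`NA` allowed; negative treated as
#'   missing).
#' @return factor with the band levels plus `missing`.
#' @export
#' @examples
#' onset_band(c(30, 31, 361, NA))
onset_band <- function(days) {
  lv <- c("0_30", "31_60", "61_90", "91_120", "121_150", "151_180",
          "181_360", "over_360", "missing")
  out <- rep("missing", length(days))
  ok <- !is.na(days) & days >= 0
  cutpts <- c(30, 60, 90, 120, 150, 180, 360)
  labs <- lv[1:8]
  idx <- findInterval(days[ok], cutpts + 1L) + 1L  # bands are upper-inclusive
  out[ok] <- labs[idx]
  factor(out, levels = lv)
}
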