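#' Read one FAERS-style ASCII table
#'
#' Quarterly FAERS releases ship each table as a delimited text file with a
#' header row, conventionally `$`-separated and without any quoting dialect.
#' All values are read verbatim as character (identifiers keep leading
#' zeros; empty fields stay `""`), with Latin-1 decoding because real files
#' contain non-UTF-8 bytes.
#'
#' @param path path to the ASCII file.
#' @param kind table kind, one of [faers_table_kinds].
#' @param delim field delimiter (default `"$"`, the FAERS convention).
#' @return a tibble with one row per data line, all columns character, and
#'   attributes `kind` and `source_path`.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("primaryid$caseid$age$sex", "1001$100$42$F"), f)
#' faers_read_table(f, "DEMO")
faers_read_table <- function(path, kind, delim = "$") {
  check_table_kind(kind)
  if (!file.exists(path)) {
    pv_validation_error(paste0("file does not exist: ", path))
  }
  tbl <- readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(),           # keep "" as empty string, never NA
    locale = readr::locale(encoding = "latin1"),
    progress = FALSE,
    show_col_types = FALSE
  )
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    pv_data_error(paste0(
      "unreadable line(s) in ", path, " at row(s): ",
      paste(unique(probs$row), collapse = ", ")
    ))
  }
  missing <- setdiff(.faers_schema_registry$mandatory[[kind]], names(tbl))
  if (length(missing) > 0) {
    pv_data_error(paste0(
      kind, " file ", path, " is missing mandatory column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  tbl <- as_tibble(tbl)
  attr(tbl, "kind") <- kind
  attr(tbl, "source_path") <- path
  tbl
}

#' Write one FAERS-style ASCII table
#'
#' Inverse of [faers_read_table()]: emits a header line plus one line per
#' row, values verbatim.  The FAERS ASCII dialect has no quoting, so a value
#' containing the delimiter cannot be represented and raises an error.
#'
#' @param tbl data frame of character (or coercible) columns.
#' @param path output path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
faers_write_table <- function(tbl, path, delim = "$") {
  tbl <- as_tibble(tbl)
  tbl[] <- lapply(tbl, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- ""
    col
  })
  hit <- vapply(tbl, function(col) any(grepl(delim, col, fixed = TRUE)), logical(1))
  if (any(hit)) {
    pv_data_error(paste0(
      "value containing the delimiter '", delim, "' in column(s): ",
      paste(names(tbl)[hit], collapse = ", "),
      " (the FAERS ASCII dialect has no quoting)"
    ))
  }
  readr::write_delim(tbl, path, delim = delim, na = "", quote = "none",
                     escape = "none", progress = FALSE)
  invisible(path)
}

#' Bundle the seven quarterly tables
#'
#' @param tables named list of tibbles; names must cover all of
#'   [faers_table_kinds] (empty tibbles allowed).
#' @param quarter quarter label such as `"2023Q1"`.
#' @return a `faers_bundle`: list with elements `quarter` and `tables`.
#' @export
faers_bundle <- function(tables, quarter) {
  missing <- setdiff(faers_table_kinds, names(tables))
  if (length(missing) > 0) {
    pv_validation_error(paste0(
      "bundle for ", quarter, " lacks table kind(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  structure(
    list(quarter = quarter, tables = tables[faers_table_kinds]),
    class = "faers_bundle"
  )
}

#' @export
print.faers_bundle <- function(x, ...) {
  counts <- vapply(x$tables, nrow, integer(1))
  cat("<faers_bundle ", x$quarter, "> ",
      paste(names(counts), counts, sep = ":", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Read all seven tables of one quarter from a directory
#'
#' Files are expected at `<dir>/<kind>_<quarter>.txt` (lower-case kind), the
#' layout written by [synth_write()].
#'
#' @param dir directory holding the quarter's files.
#' @param quarter quarter label, e.g. `"2023Q1"`.
#' @param delim field delimiter.
#' @return a `faers_bundle`.
#' @export
faers_read_quarter <- function(dir, quarter, delim = "$") {
  if (!dir.exists(dir)) {
    pv_validation_error(paste0("input directory does not exist: ", dir))
  }
  tables <- lapply(faers_table_kinds, function(kind) {
    path <- file.path(dir, paste0(tolower(kind), "_", quarter, ".txt"))
    if (!file.exists(path)) {
      pv_validation_error(paste0("missing table file: ", path))
    }
    faers_read_table(path, kind, delim = delim)
  })
  names(tables) <- faers_table_kinds
  faers_bundle(tables, quarter)
}

# bind one table kind across bundles, tagging the quarter
bind_kind <- function(bundles, kind) {
  pieces <- lapply(bundles, function(b) {
    tbl <- b$tables[[kind]]
    if (nrow(tbl) > 0) tbl$quarter <- b$quarter
    tbl
  })
  bind_rows(pieces)
}

#' Assemble per-case report records from quarterly bundles
#'
#' Joins the seven raw tables into one tibble of safety reports, one row per
#' distinct `primaryid`.  Rows in non-DEMO tables whose `primaryid` has no
#' DEMO entry are orphans: they are dropped and counted.  A duplicated
#' `primaryid` within DEMO keeps the last occurrence (with a warning).
#'
#' Typed fields derived from the raw strings: report/event dates, age in
#' years (via [age_harmonize()]), sex (`F`/`M`/`unknown`), weight in kg,
#' reporter occupation, seriousness (`TRUE` when the report has at least one
#' outcome record), therapy start (earliest across suspect drugs) and onset
#' days (event date minus therapy start).
#'
#' @param bundles list of `faers_bundle` objects (or a single bundle).
#' @return tibble of cases with list-columns `drug_names`, `drug_roles`,
#'   `drug_indications`, `events`, `outcomes`, and attributes
#'   `orphan_counts` (named integer, per table kind) and `n_demo_duplicates`.
#' @export
faers_assemble <- function(bundles) {
  if (inherits(bundles, "faers_bundle")) bundles <- list(bundles)
  if (length(bundles) == 0) {
    pv_validation_error("`bundles` must contain at least one quarter bundle")
  }

  demo <- bind_kind(bundles, "DEMO")
  if (nrow(demo) == 0) {
    pv_data_error("no DEMO rows found in the supplied bundles")
  }
  n_dup_demo <- sum(duplicated(demo$primaryid))
  if (n_dup_demo > 0) {
    warn(paste0(n_dup_demo, " duplicated primaryid(s) in DEMO; keeping the ",
                "last occurrence of each"))
    demo <- demo[!duplicated(demo$primaryid, fromLast = TRUE), ]
  }
  known <- demo$primaryid

  pick <- function(tbl, col) if (col %in% names(tbl)) tbl[[col]] else
    rep("", nrow(tbl))

  take_kind <- function(kind) {
    tbl <- bind_kind(bundles, kind)
    orphan <- !(tbl$primaryid %in% known)
    list(rows = tbl[!orphan, , drop = FALSE], n_orphan = sum(orphan))
  }
  drug <- take_kind("DRUG"); reac <- take_kind("REAC")
  outc <- take_kind("OUTC"); ther <- take_kind("THER")
  indi <- take_kind("INDI"); rpsr <- take_kind("RPSR")
  orphan_counts <- c(
    DRUG = drug$n_orphan, REAC = reac$n_orphan, OUTC = outc$n_orphan,
    THER = ther$n_orphan, INDI = indi$n_orphan, RPSR = rpsr$n_orphan
  )

  # drug entries with per-entry indication and therapy start attached by
  # (primaryid, drug sequence number)
  d <- drug$rows
  drugs <- tibble(
    primaryid = d$primaryid,
    drug_seq = pick(d, "drug_seq"),
    name_raw = str_squish_lower(pick(d, "drugname")),
    role = toupper(trimws(pick(d, "role_cod")))
  )
  ind <- indi$rows
  if (nrow(ind) > 0) {
    drugs <- left_join(
      drugs,
      tibble(primaryid = ind$primaryid,
             drug_seq = pick(ind, "indi_drug_seq"),
             indication = trimws(pick(ind, "indi_pt"))) |>
        distinct(.data$primaryid, .data$drug_seq, .keep_all = TRUE),
      by = c("primaryid", "drug_seq")
    )
  } else {
    drugs$indication <- NA_character_
  }
  th <- ther$rows
  if (nrow(th) > 0) {
    drugs <- left_join(
      drugs,
      tibble(primaryid = th$primaryid,
             drug_seq = pick(th, "dsg_drug_seq"),
             start_dt = parse_faers_date(pick(th, "start_dt"))) |>
        distinct(.data$primaryid, .data$drug_seq, .keep_all = TRUE),
      by = c("primaryid", "drug_seq")
    )
  } else {
    drugs$start_dt <- as.Date(NA)
  }

  split_by_id <- function(ids, values) {
    sp <- vctrs::vec_split(values, ids)
    setNames(sp$val, sp$key)
  }
  id_list <- function(lst, ids, empty) {
    out <- lst[ids]
    miss <- vapply(out, is.null, logical(1))
    out[miss] <- list(empty)
    unname(out)
  }

  drug_names <- split_by_id(drugs$primaryid, drugs$name_raw)
  drug_roles <- split_by_id(drugs$primaryid, drugs$role)
  drug_inds  <- split_by_id(drugs$primaryid, drugs$indication)
  events     <- split_by_id(reac$rows$primaryid,
                            trimws(pick(reac$rows, "pt")))
  outcomes   <- split_by_id(outc$rows$primaryid,
                            toupper(trimws(pick(outc$rows, "outc_cod"))))

  # earliest therapy start across suspect-role entries of each report
  sus <- drugs[drugs$role %in% c("PS", "SS") & !is.na(drugs$start_dt), ]
  ther_start <- rep(as.Date(NA), nrow(demo))
  if (nrow(sus) > 0) {
    agg <- sus |>
      group_by(.data$primaryid) |>
      summarise(start = min(.data$start_dt), .groups = "drop")
    ther_start[match(agg$primaryid, demo$primaryid)] <- agg$start
  }

  sex_raw <- toupper(trimws(pick(demo, "sex")))
  occp <- toupper(trimws(pick(demo, "occp_cod")))
  reporter_map <- c(CN = "consumer", MD = "physician", PH = "pharmacist",
                    OT = "other_health_professional",
                    HP = "other_health_professional", LW = "other")
  reporter <- unname(reporter_map[occp])
  reporter[is.na(reporter)] <- "not_specified"

  cases <- tibble(
    primaryid = demo$primaryid,
    caseid = pick(demo, "caseid"),
    report_date = parse_faers_date(pick(demo, "fda_dt")),
    event_date = parse_faers_date(pick(demo, "event_dt")),
    age_years = age_harmonize(suppressWarnings(as.numeric(pick(demo, "age"))),
                              toupper(trimws(pick(demo, "age_cod")))),
    sex = ifelse(sex_raw %in% c("F", "M"), sex_raw, "unknown"),
    weight_kg = suppressWarnings(as.numeric(pick(demo, "wt"))),
    reporter = reporter,
    country_occur = trimws(pick(demo, "occr_country")),
    country_report = trimws(pick(demo, "reporter_country")),
    drug_names = id_list(drug_names, demo$primaryid, character(0)),
    drug_roles = id_list(drug_roles, demo$primaryid, character(0)),
    drug_indications = id_list(drug_inds, demo$primaryid, character(0)),
    events = id_list(events, demo$primaryid, character(0)),
    outcomes = id_list(outcomes, demo$primaryid, character(0)),
    therapy_start = ther_start
  )
  cases$serious <- lengths(cases$outcomes) > 0
  cases$onset_days <- compute_onset_days(cases$therapy_start, cases$event_date)

  attr(cases, "orphan_counts") <- orphan_counts
  attr(cases, "n_demo_duplicates") <- n_dup_demo
  cases
}

# trim + squeeze internal whitespace + lower-case (drug-name normal form)
str_squish_lower <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}
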