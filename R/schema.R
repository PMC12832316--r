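#' FAERS quarterly table kinds
#'
#' The seven table kinds that make up one quarterly release of a FAERS-style
#' spontaneous reporting database.
#'
#' @export
faers_table_kinds <- c("DEMO", "DRUG", "REAC", "OUTC", "THER", "INDI", "RPSR")

# versioned column registry.  These are the columns the pipeline relies on;
# extra columns present in a file are carried through untouched because the
# quarterly schemas drift over time.
.faers_schema_registry <- list(
  version = "pvsignal-schema-1",
  columns = list(
    DEMO = c("primaryid", "caseid", "caseversion", "fda_dt", "event_dt",
             "age", "age_cod", "sex", "wt", "wt_cod", "occp_cod",
             "occr_country", "reporter_country"),
    DRUG = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname"),
    REAC = c("primaryid", "caseid", "pt"),
    OUTC = c("primaryid", "caseid", "outc_cod"),
    THER = c("primaryid", "caseid", "dsg_drug_seq", "start_dt", "end_dt"),
    INDI = c("primaryid", "caseid", "indi_drug_seq", "indi_pt"),
    RPSR = c("primaryid", "caseid", "rpsr_cod")
  ),
  # columns that must be present for the pipeline to work at all
  mandatory = list(
    DEMO = c("primaryid", "caseid"),
    DRUG = c("primaryid"),
    REAC = c("primaryid"),
    OUTC = c("primaryid"),
    THER = c("primaryid"),
    INDI = c("primaryid"),
    RPSR = c("primaryid")
  )
)

#' Declared column schema for a FAERS table kind
#'
#' @param kind one of [faers_table_kinds].
#' @return character vector of column names the pipeline expects for `kind`.
#'   Files may carry additional columns; they are preserved as-is.
#' @export
faers_schema <- function(kind) {
  kind <- match.arg(kind, faers_table_kinds)
  .faers_schema_registry$columns[[kind]]
}

check_table_kind <- function(kind) {
  if (length(kind) != 1L || !kind %in% faers_table_kinds) {
    pv_validation_error(paste0(
      "`kind` must be one of: ", paste(faers_table_kinds, collapse = ", ")
    ))
  }
  kind
}
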