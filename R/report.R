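#' Build and validate a pipeline run configuration
#'
#' @param x path to a YAML file or a named list.  Recognised keys:
#'   `data_dir`, `quarters` (character vector), `delimiter`, `drugs`
#'   (named list: canonical name -> character vector of synonyms),
#'   `synonym_file` (alternative to `drugs`), `dictionary_file`,
#'   `indication_terms`, `adult_only`, `comparator_mode`, `min_a`,
#'   `subgroup_axes`, `thresholds` (named overrides of
#'   [signal_thresholds()]), `out_dir`, `seed`.
#' @return a validated `pv_config` list with defaults filled in.
#' @export
pv_config <- function(x) {
  cfg <- if (is.character(x)) {
    if (!file.exists(x)) pv_validation_error(paste0("config file not found: ", x))
    yaml::read_yaml(x)
  } else {
    x
  }
  defaults <- list(
    delimiter = "$", indication_terms = "Alopecia areata",
    adult_only = FALSE, comparator_mode = "full_database", min_a = 3,
    subgroup_axes = c("gender", "age_band", "seriousness"),
    thresholds = list(), seed = 1
  )
  cfg <- modifyList(defaults, cfg)
  for (key in c("data_dir", "out_dir")) {
    if (is.null(cfg[[key]])) {
      pv_validation_error(paste0("config key '", key, "' is required"))
    }
  }
  if (!dir.exists(cfg$data_dir)) {
    pv_validation_error(paste0("data_dir does not exist: ", cfg$data_dir))
  }
  if (is.null(cfg$quarters) || length(cfg$quarters) == 0) {
    pv_validation_error("config must list at least one quarter")
  }
  for (key in c("synonym_file", "dictionary_file")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      pv_validation_error(paste0(key, " does not exist: ", cfg[[key]]))
    }
  }
  if (is.null(cfg$drugs) && is.null(cfg$synonym_file)) {
    pv_validation_error("config needs 'drugs' (name -> synonyms) or 'synonym_file'")
  }
  cfg$thresholds <- do.call(signal_thresholds, cfg$thresholds)
  structure(cfg, class = "pv_config")
}

config_synonym_map <- function(config) {
  if (!is.null(config$synonym_file)) {
    read_synonym_map(config$synonym_file)
  } else {
    canon <- rep(names(config$drugs), lengths(config$drugs) + 1)
    syn <- unlist(lapply(names(config$drugs), function(nm)
      c(nm, config$drugs[[nm]])), use.names = FALSE)
    synonym_map(canon, syn)
  }
}

config_drug_names <- function(config) {
  if (!is.null(config$drugs)) names(config$drugs)
  else unique(config_synonym_map(config)$canonical)
}

# snapshot the resolved configuration next to the outputs (audit trail)
write_resolved_config <- function(config, out_dir) {
  snap <- unclass(config)
  snap$thresholds <- unclass(snap$thresholds)
  yaml::write_yaml(snap, file.path(out_dir, "resolved_config.yaml"))
}

#' Serialize / load a cleaned case store
#'
#' The case tibble is relational under the hood (drugs, events and
#' outcomes are one-to-many); the store is four delimited text files in a
#' directory.
#'
#' @param cases case tibble.
#' @param dir store directory.
#' @return `dir` (write) or the case tibble (read).
#' @export
write_case_store <- function(cases, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scalars <- cases[, !vapply(cases, is.list, logical(1)), drop = FALSE]
  readr::write_tsv(scalars, file.path(dir, "cases.tsv"), progress = FALSE)
  lens <- lengths(cases$drug_names)
  drugs <- tibble(
    primaryid = rep(cases$primaryid, lens),
    name_raw = unlist(cases$drug_names, use.names = FALSE),
    canonical = if ("drug_canonical" %in% names(cases))
      unlist(cases$drug_canonical, use.names = FALSE) else NA_character_,
    role = unlist(cases$drug_roles, use.names = FALSE),
    indication = unlist(cases$drug_indications, use.names = FALSE)
  )
  readr::write_tsv(drugs, file.path(dir, "drugs.tsv"), progress = FALSE)
  readr::write_tsv(flatten_listcol(cases$primaryid, cases$events, "pt"),
                   file.path(dir, "events.tsv"), progress = FALSE)
  readr::write_tsv(flatten_listcol(cases$primaryid, cases$outcomes, "outc_cod"),
                   file.path(dir, "outcomes.tsv"), progress = FALSE)
  invisible(dir)
}

#' @rdname write_case_store
#' @export
read_case_store <- function(dir) {
  scalars <- readr::read_tsv(file.path(dir, "cases.tsv"),
                             show_col_types = FALSE, progress = FALSE,
                             col_types = readr::cols(
                               primaryid = "c", caseid = "c",
                               report_date = readr::col_date(),
                               event_date = readr::col_date(),
                               therapy_start = readr::col_date(),
                               sex = "c", reporter = "c",
                               country_occur = "c", country_report = "c",
                               serious = "l", .default = "d"))
  relist_col <- function(path, col) {
    tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = "c"))
    sp <- vctrs::vec_split(tbl[[col]], tbl$primaryid)
    lst <- setNames(sp$val, sp$key)[scalars$primaryid]
    lst[vapply(lst, is.null, logical(1))] <- list(character(0))
    unname(lst)
  }
  drugs <- readr::read_tsv(file.path(dir, "drugs.tsv"),
                           show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  sp <- vctrs::vec_split(drugs[c("name_raw", "canonical", "role",
                                 "indication")], drugs$primaryid)
  dmap <- setNames(sp$val, sp$key)[scalars$primaryid]
  null_d <- vapply(dmap, is.null, logical(1))
  pull_col <- function(col) {
    out <- lapply(dmap, function(d) if (is.null(d)) character(0) else d[[col]])
    unname(out)
  }
  cases <- scalars
  cases$drug_names <- pull_col("name_raw")
  cases$drug_canonical <- pull_col("canonical")
  cases$drug_roles <- pull_col("role")
  cases$drug_indications <- pull_col("indication")
  cases$events <- relist_col(file.path(dir, "events.tsv"), "pt")
  cases$outcomes <- relist_col(file.path(dir, "outcomes.tsv"), "outc_cod")
  cases$onset_days <- as.integer(cases$onset_days)
  cases
}

#' Run the cleaning stage
#'
#' Reads the configured quarters, assembles cases, standardizes drug
#' names, recodes implausible values, deduplicates, and writes the cleaned
#' case store plus a cleaning report and a flowchart-style attrition
#' ledger (raw -> deduplicated counts).
#'
#' @param config a [pv_config()] (or list / YAML path accepted by it).
#' @return the cleaned case tibble, invisibly; outputs under
#'   `<out_dir>/cleaned/`.
#' @export
pv_run_clean <- function(config) {
  config <- pv_config(config)
  bundles <- lapply(config$quarters, function(q)
    faers_read_quarter(config$data_dir, q, delim = config$delimiter))
  cases <- faers_assemble(bundles)
  orphans <- sum(attr(cases, "orphan_counts"))
  n_raw <- nrow(cases)
  cases <- faers_standardize_drugs(cases, config_synonym_map(config))
  cases <- faers_recode_implausible(cases)
  cases <- faers_dedup(cases)
  rep <- cleaning_report(cases)

  out_dir <- file.path(config$out_dir, "cleaned")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_case_store(cases, out_dir)
  jsonlite::write_json(rep, file.path(out_dir, "cleaning_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  ledger <- tibble(
    stage = c("raw_rows", "orphan_rows_excluded", "assembled_cases",
              "after_deduplication"),
    count = c(n_raw + orphans, orphans, n_raw, rep$output_cases)
  )
  readr::write_tsv(ledger, file.path(out_dir, "attrition_ledger.tsv"),
                   progress = FALSE)
  write_resolved_config(config, config$out_dir)
  invisible(cases)
}

# Table-1-style block for one cohort: categorical rows + continuous blocks
descriptive_tables <- function(cohort_map) {
  groups <- names(cohort_map)
  one_group <- function(nm) {
    cases <- cohort_map[[nm]]
    cases$age_group <- as.character(age_band(cases$age_years))
    cases$onset_group <- as.character(onset_band(cases$onset_days))
    cases$seriousness <- ifelse(cases$serious, "serious", "non_serious")
    cat_vars <- c("sex", "age_group", "reporter", "seriousness",
                  "onset_group")
    cats <- bind_rows(lapply(cat_vars, function(v) {
      summarize_categorical(cases, !!rlang::sym(v)) |>
        mutate(variable = v, group = nm)
    }))
    cont <- bind_rows(
      summarize_continuous(cases$age_years) |> mutate(variable = "age_years"),
      summarize_continuous(as.numeric(cases$onset_days)) |>
        mutate(variable = "onset_days"),
      summarize_continuous(cases$weight_kg) |> mutate(variable = "weight_kg")
    ) |> mutate(group = nm)
    list(categorical = cats, continuous = cont)
  }
  parts <- lapply(groups, one_group)
  list(
    categorical = bind_rows(lapply(parts, `[[`, "categorical")),
    continuous = bind_rows(lapply(parts, `[[`, "continuous"))
  )
}

# the paper-style between-drug comparisons (first two cohorts)
comparison_tests <- function(cohort_map) {
  if (length(cohort_map) < 2) return(tibble())
  a <- cohort_map[[1]]; b <- cohort_map[[2]]
  res <- list()
  ser <- rbind(c(sum(a$serious), sum(!a$serious)),
               c(sum(b$serious), sum(!b$serious)))
  res$seriousness <- compare_categorical(ser)
  sex_tab <- rbind(table(factor(a$sex, c("F", "M", "unknown"))),
                   table(factor(b$sex, c("F", "M", "unknown"))))
  keep <- colSums(sex_tab) > 0
  if (sum(keep) >= 2) res$sex <- compare_categorical(sex_tab[, keep])
  if (sum(!is.na(a$age_years)) > 0 && sum(!is.na(b$age_years)) > 0) {
    res$age <- compare_continuous(a$age_years, b$age_years)
  }
  if (sum(!is.na(a$onset_days)) > 0 && sum(!is.na(b$onset_days)) > 0) {
    res$onset <- compare_continuous(as.numeric(a$onset_days),
                                    as.numeric(b$onset_days))
  }
  bind_rows(res, .id = "variable")
}

#' Run the analysis stage
#'
#' Consumes the cleaned case store and emits, per configured drug:
#' demographic summary tables, the SOC distribution, the whole-cohort
#' four-algorithm screen, per-axis subgroup screens and heatmap matrices;
#' plus between-drug comparison tests and a run manifest.  Descriptive
#' tables cover all ages; the `adult_only` flag applies to the signal
#' cohort, and the output notes when pediatric reports were present but
#' excluded from screening.
#'
#' @param config a [pv_config()].
#' @param cases optional cleaned case tibble (defaults to reading the
#'   store written by [pv_run_clean()]).
#' @return invisible list of per-drug results.
#' @export
pv_run_analyze <- function(config, cases = NULL) {
  config <- pv_config(config)
  if (is.null(cases)) {
    store <- file.path(config$out_dir, "cleaned")
    if (!dir.exists(store)) {
      pv_validation_error(paste0("no cleaned case store at ", store,
                                 "; run pv_run_clean() first"))
    }
    cases <- read_case_store(store)
  }
  dict <- if (!is.null(config$dictionary_file)) {
    read_meddra_dict(config$dictionary_file)
  } else {
    NULL
  }
  out_dir <- file.path(config$out_dir, "analysis")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  drugs <- config_drug_names(config)

  # descriptive cohorts keep all ages; signal cohorts honour adult_only
  desc_map <- lapply(drugs, function(d)
    select_cohort(cases, d, config$indication_terms, adult_only = FALSE))
  names(desc_map) <- drugs
  desc <- descriptive_tables(desc_map)
  readr::write_tsv(desc$categorical,
                   file.path(out_dir, "table1_categorical.tsv"),
                   progress = FALSE)
  readr::write_tsv(desc$continuous,
                   file.path(out_dir, "table1_continuous.tsv"),
                   progress = FALSE)
  tests <- comparison_tests(desc_map)
  if (nrow(tests) > 0) {
    readr::write_tsv(tests, file.path(out_dir, "comparison_tests.tsv"),
                     progress = FALSE)
  }

  results <- list()
  for (d in drugs) {
    cohort <- select_cohort(cases, d, config$indication_terms,
                            adult_only = config$adult_only)
    n_ped <- sum(!is.na(desc_map[[d]]$age_years) &
                   desc_map[[d]]$age_years < 18)
    background <- if (config$comparator_mode == "within_indication") {
      has_ind <- map_lgl(cases$drug_indications, function(x)
        any(str_squish_lower(x) %in% str_squish_lower(config$indication_terms),
            na.rm = TRUE))
      cases[has_ind | cases$primaryid %in% cohort$primaryid, , drop = FALSE]
    } else {
      cases
    }
    if (!is.null(dict)) {
      ev <- expand_events(cohort, dict)
      readr::write_tsv(soc_distribution(ev),
                       file.path(out_dir, paste0("table2_soc_", d, ".tsv")),
                       progress = FALSE)
    }
    scr <- run_screen(cohort, background, dict = dict,
                      thresholds = config$thresholds, min_a = config$min_a,
                      comparator_mode = config$comparator_mode)
    readr::write_tsv(as_tibble(scr),
                     file.path(out_dir, paste0("screen_", d, ".tsv")),
                     progress = FALSE)
    subs <- list()
    for (axis in config$subgroup_axes) {
      sg <- subgroup_screen(cohort, background, axis = axis, dict = dict,
                            thresholds = config$thresholds,
                            min_a = config$min_a)
      hm <- tryCatch(heatmap_matrix(sg), pv_data_error = function(e) NULL)
      if (!is.null(hm)) {
        write_heatmap_matrix(hm, file.path(out_dir,
                                           paste0("heatmap_", d, "_", axis,
                                                  ".tsv")))
      }
      subs[[axis]] <- sg
    }
    results[[d]] <- list(cohort_size = nrow(cohort),
                         pediatric_excluded = if (config$adult_only) n_ped else 0L,
                         screen = scr, subgroups = subs)
  }

  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.json"))
  manifest <- list(
    package = "pvsignal",
    version = as.character(utils::packageVersion("pvsignal")),
    seed = config$seed,
    comparator_mode = config$comparator_mode,
    adult_only = config$adult_only,
    cohort_sizes = lapply(results, `[[`, "cohort_size"),
    pediatric_excluded = lapply(results, `[[`, "pediatric_excluded"),
    files = as.list(setNames(unname(tools::md5sum(files)), basename(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_resolved_config(config, config$out_dir)
  invisible(results)
}
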