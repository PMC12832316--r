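`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal case tibble builder: fills every column the pipeline touches so
# individual tests only spell out the fields they care about
mk_cases <- function(n,
                     primaryid = as.character(1000 + seq_len(n)),
                     caseid = as.character(100 + seq_len(n)),
                     report_date = as.Date("2023-06-01") + seq_len(n) - 1,
                     age_years = rep(40, n),
                     sex = rep("F", n),
                     serious = rep(FALSE, n),
                     events = rep(list("PT_A"), n),
                     drug_names = rep(list("drugx"), n),
                     drug_canonical = drug_names,
                     drug_roles = rep(list("PS"), n),
                     drug_indications = rep(list("Alopecia areata"), n),
                     outcomes = rep(list(character(0)), n),
                     onset_days = rep(NA_integer_, n),
                     weight_kg = rep(NA_real_, n)) {
  tibble::tibble(
    primaryid = primaryid, caseid = caseid, report_date = report_date,
    event_date = report_date, age_years = age_years, sex = sex,
    weight_kg = weight_kg, reporter = "consumer", country_occur = "US",
    country_report = "US", drug_names = drug_names,
    drug_roles = drug_roles, drug_indications = drug_indications,
    events = events, outcomes = outcomes,
    therapy_start = as.Date(NA), serious = serious,
    onset_days = onset_days, drug_canonical = drug_canonical
  )
}

# deterministic random contingency tables with all cells positive
random_tables <- function(n, seed, max_cell = 500) {
  set.seed(seed)
  contingency_table(
    a = sample(1:max_cell, n, replace = TRUE),
    b = sample(1:max_cell, n, replace = TRUE),
    c = sample(1:max_cell, n, replace = TRUE),
    d = sample(1:(20 * max_cell), n, replace = TRUE)
  )
}

# run the full file-backed pipeline on a generated database and return the
# screen for the first target drug plus the ground truth
run_pipeline <- function(cfg, min_a = 3) {
  sim <- synth_generate(cfg)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  synth_write(sim$bundles, dir)
  quarters <- sub(".*demo_(.*)[.]txt$", "\\1",
                  list.files(dir, pattern = "^demo"))
  bundles <- lapply(quarters, function(q) faers_read_quarter(dir, q))
  cases <- faers_assemble(bundles)
  targets <- cfg$target_drugs
  map <- synonym_map(
    rep(vapply(targets, `[[`, "", "name"),
        vapply(targets, function(t) length(t$synonyms %||% character(0)),
               integer(1))),
    unlist(lapply(targets, function(t) t$synonyms %||% character(0)))
  )
  cases <- faers_standardize_drugs(cases, map)
  cases <- faers_recode_implausible(cases)
  cases <- faers_dedup(cases)
  cohort <- select_cohort(cases, targets[[1]]$name)
  list(
    cases = cases, cohort = cohort, sim = sim,
    screen = run_screen(cohort, cases, dict = sim$dict, min_a = min_a)
  )
}

# deduplication idempotence/order-invariance compares the retained data,
# not the per-run bookkeeping attribute
strip_report <- function(x) {
  attr(x, "cleaning_report") <- NULL
  as.data.frame(x)
}
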