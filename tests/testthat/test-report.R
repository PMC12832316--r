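make_run_dirs <- function(seed = 3, n_reports = 1500, env = parent.frame()) {
  data_dir <- withr::local_tempdir(.local_envir = env)
  out_dir <- withr::local_tempdir(.local_envir = env)
  cfg <- synth_scenario_aa(seed = seed, n_reports = n_reports)
  sim <- synth_generate(cfg)
  synth_write(sim$bundles, data_dir)
  write_meddra_dict(sim$dict, file.path(data_dir, "dict.tsv"))
  quarters <- sub(".*demo_(.*)[.]txt$", "\\1",
                  list.files(data_dir, pattern = "^demo"))
  run_cfg <- list(
    data_dir = data_dir, out_dir = out_dir, quarters = quarters,
    drugs = list(baricitinib = "olumiant",
                 tofacitinib = c("xeljanz", "xeljanz xr")),
    dictionary_file = file.path(data_dir, "dict.tsv"),
    min_a = 2
  )
  list(cfg = run_cfg, sim = sim, out = out_dir)
}

test_that("the cleaning stage writes a reconciling attrition ledger", {
  rd <- make_run_dirs()
  cases <- pv_run_clean(rd$cfg)
  led <- readr::read_tsv(file.path(rd$out, "cleaned", "attrition_ledger.tsv"),
                         show_col_types = FALSE)
  n <- setNames(led$count, led$stage)
  expect_equal(unname(n["assembled_cases"] - n["after_deduplication"]),
               rd$sim$truth$duplicates_removed)
  expect_equal(unname(n["after_deduplication"]), nrow(cases))
  expect_true(file.exists(file.path(rd$out, "cleaned",
                                    "cleaning_report.json")))
  expect_true(file.exists(file.path(rd$out, "resolved_config.yaml")))
  # the cleaned store round-trips
  back <- read_case_store(file.path(rd$out, "cleaned"))
  expect_equal(nrow(back), nrow(cases))
  expect_equal(back$events[match(cases$primaryid, back$primaryid)],
               cases$events)
  # re-cleaning the cleaned store removes nothing further
  expect_equal(cleaning_report(faers_dedup(back))$duplicates_removed, 0)
})

test_that("the analysis stage emits tables, screens and a manifest", {
  rd <- make_run_dirs(seed = 6)
  pv_run_clean(rd$cfg)
  res <- pv_run_analyze(rd$cfg)
  adir <- file.path(rd$out, "analysis")
  for (f in c("table1_categorical.tsv", "table1_continuous.tsv",
              "comparison_tests.tsv", "table2_soc_baricitinib.tsv",
              "screen_baricitinib.tsv", "screen_tofacitinib.tsv",
              "manifest.json")) {
    expect_true(file.exists(file.path(adir, f)), info = f)
  }
  # the between-drug seriousness test is present with method and p
  tests <- readr::read_tsv(file.path(adir, "comparison_tests.tsv"),
                           show_col_types = FALSE)
  ser <- tests[tests$variable == "seriousness", ]
  expect_equal(nrow(ser), 1)
  expect_true(ser$method %in% c("chi2", "fisher"))
  expect_true(ser$p_value >= 0 && ser$p_value <= 1)
  # SOC percentages cover the whole cohort
  soc <- readr::read_tsv(file.path(adir, "table2_soc_baricitinib.tsv"),
                         show_col_types = FALSE)
  expect_lt(abs(sum(soc$pct) - 100), 0.05)
  manifest <- jsonlite::read_json(file.path(adir, "manifest.json"))
  expect_equal(manifest$cohort_sizes$baricitinib,
               unname(res$baricitinib$cohort_size))
})

test_that("analysis outputs are reproducible byte for byte", {
  rd <- make_run_dirs(seed = 9, n_reports = 800)
  pv_run_clean(rd$cfg)
  pv_run_analyze(rd$cfg)
  adir <- file.path(rd$out, "analysis")
  first <- tools::md5sum(list.files(adir, full.names = TRUE))
  pv_run_analyze(rd$cfg)
  second <- tools::md5sum(list.files(adir, full.names = TRUE))
  expect_equal(first, second)
})

test_that("configuration problems fail fast with classed errors", {
  expect_error(pv_config(list(out_dir = tempdir())),
               class = "pv_validation_error")
  expect_error(pv_config(list(data_dir = "/nonexistent/dir",
                              out_dir = tempdir(), quarters = "2023Q1",
                              drugs = list(a = "b"))),
               class = "pv_validation_error")
  d <- withr::local_tempdir()
  expect_error(pv_config(list(data_dir = d, out_dir = d,
                              quarters = "2023Q1")),
               class = "pv_validation_error", regexp = "drugs")
  expect_error(
    pv_run_analyze(list(data_dir = d, out_dir = file.path(d, "fresh"),
                        quarters = "2023Q1", drugs = list(a = "b"))),
    class = "pv_validation_error", regexp = "cleaned")
})
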