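test_that("the synthetic dictionary is deterministic and total", {
  d1 <- synth_dictionary(100, 27, seed = 4)
  d2 <- synth_dictionary(100, 27, seed = 4)
  expect_equal(as.data.frame(d1), as.data.frame(d2))
  expect_false(identical(as.data.frame(d1),
                         as.data.frame(synth_dictionary(100, 27, seed = 5))))
  expect_equal(anyDuplicated(d1$pt), 0)
  expect_equal(nrow(d1), 100)
  # the official organ-class label universe comes first
  expect_true(all(d1$soc %in% pvsignal:::.soc_labels))
  expect_true("Infections and infestations" %in% d1$soc)
  big <- synth_dictionary(300, 40, seed = 1)
  expect_equal(length(unique(big$soc)), 40)
})

test_that("generation is byte-identical under a fixed config and seed", {
  cfg <- synth_config(seed = 13, n_reports = 400)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  synth_write(synth_generate(cfg)$bundles, d1)
  synth_write(synth_generate(cfg)$bundles, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("implanted multipliers and duplicate rates hit their targets", {
  # rho = 1 everywhere: observed/expected for a named pair stays near 1
  cfg <- synth_config(seed = 29, n_reports = 50000)
  sim <- synth_generate(cfg)
  cases <- faers_dedup(faers_assemble(sim$bundles))
  cases <- faers_standardize_drugs(cases,
                                   synonym_map("baricitinib", "olumiant"))
  cohort <- select_cohort(cases, "baricitinib")
  t <- build_contingency(cohort, cases, "PT_0100")
  rel <- t$a / t$expected
  se <- 1 / sqrt(t$a)
  expect_lt(abs(log(rel)), 3 * se)

  # duplicate versions arrive at the configured binomial rate
  cfg2 <- synth_config(seed = 31, n_reports = 10000, duplicate_rate = 0.1,
                       followup_rate = 0)
  sim2 <- synth_generate(cfg2)
  n_dup <- sim2$truth$duplicates_removed
  se_dup <- sqrt(10000 * 0.1 * 0.9)
  expect_lt(abs(n_dup - 1000), 3 * se_dup)
  # and deduplication removes exactly those
  cases2 <- faers_dedup(faers_assemble(sim2$bundles))
  expect_equal(cleaning_report(cases2)$duplicates_removed, n_dup)
})

test_that("an infeasible implantation is rejected", {
  expect_error(
    synth_generate(synth_config(
      seed = 1, n_reports = 100, n_drugs = 2, n_pts = 5,
      target_drugs = list(list(name = "baricitinib", share = 0.9)),
      implanted = data.frame(drug = "baricitinib", pt = "PT_0001",
                             rho = 1e6))),
    class = "pv_validation_error")
  expect_error(synth_config(seed = 1, duplicate_rate = 1.5),
               class = "pv_validation_error")
  expect_error(
    synth_config(implanted = data.frame(drug = "baricitinib",
                                        pt = "PT_9999", rho = 2)),
    class = "pv_validation_error")
})

test_that("the two-drug study scenario has the configured structure", {
  for (s in 0:2) {
    pipe <- local({
      cfg <- synth_scenario_aa(seed = s)
      sim <- synth_generate(cfg)
      cases <- faers_assemble(sim$bundles)
      map <- synonym_map(c("baricitinib", "tofacitinib", "tofacitinib"),
                         c("olumiant", "xeljanz", "xeljanz xr"))
      cases <- faers_dedup(faers_recode_implausible(
        faers_standardize_drugs(cases, map)))
      list(b = select_cohort(cases, "baricitinib"),
           t = select_cohort(cases, "tofacitinib"), dict = sim$dict)
    })
    expect_gt(nrow(pipe$b), 0)
    expect_gt(nrow(pipe$t), 0)
    # serious fraction of drug one within a binomial band around 0.1545
    expect_gt(mean(pipe$b$serious), 0.10)
    expect_lt(mean(pipe$b$serious), 0.21)
    # drug two carries about three events per report
    ev_t <- expand_events(pipe$t, pipe$dict)
    expect_gt(nrow(ev_t) / nrow(pipe$t), 2.7)
    expect_lt(nrow(ev_t) / nrow(pipe$t), 3.3)
    # drug one hides about half its ages, drug two about a tenth
    expect_gt(mean(is.na(pipe$b$age_years)), 0.40)
    expect_lt(mean(is.na(pipe$t$age_years)), 0.20)
  }
})
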