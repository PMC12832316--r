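# the official system-organ-class label universe used before synthetic
# labels when building a stand-in PT->SOC dictionary
.soc_labels <- c(
  "General disorders and administration site conditions",
  "Infections and infestations",
  "Investigations",
  "Skin and subcutaneous tissue disorders",
  "Nervous system disorders",
  "Injury, poisoning and procedural complications",
  "Gastrointestinal disorders",
  "Surgical and medical procedures",
  "Musculoskeletal and connective tissue disorders",
  "Respiratory, thoracic and mediastinal disorders",
  "Neoplasms benign, malignant and unspecified (incl cysts and polyps)",
  "Vascular disorders",
  "Psychiatric disorders",
  "Blood and lymphatic system disorders",
  "Cardiac disorders",
  "Eye disorders",
  "Renal and urinary disorders",
  "Reproductive system and breast disorders",
  "Metabolism and nutrition disorders",
  "Immune system disorders",
  "Hepatobiliary disorders",
  "Ear and labyrinth disorders",
  "Pregnancy, puerperium and perinatal conditions",
  "Endocrine disorders",
  "Social circumstances",
  "Product issues",
  "Congenital, familial and genetic disorders"
)

#' Synthetic preferred-term dictionary
#'
#' Deterministic stand-in for a licensed MedDRA PT->SOC table: `n_pts`
#' synthetic preferred terms (`PT_0001`, ...) each assigned to exactly one
#' system organ class.  SOC labels are drawn from the 27 official organ
#' class names first, then synthetic labels.
#'
#' @param n_pts number of preferred terms.
#' @param n_socs number of organ classes (max 27 official labels, synthetic
#'   beyond that).
#' @param seed seed controlling the PT->SOC assignment.
#' @return a `meddra_dict`.
#' @export
synth_dictionary <- function(n_pts = 250, n_socs = 27, seed = 1) {
  socs <- if (n_socs <= length(.soc_labels)) {
    .soc_labels[seq_len(n_socs)]
  } else {
    c(.soc_labels,
      paste0("Synthetic organ class ", seq_len(n_socs - length(.soc_labels))))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pt <- sprintf("PT_%04d", seq_len(n_pts))
  assignment <- sample(rep_len(seq_len(n_socs), n_pts))
  meddra_dict(pt, socs[assignment],
              version = paste0("synthetic-", seed))
}

# default demographic profile; targets may override any field
.default_profile <- function() {
  list(
    sex_mix = c(F = 0.45, M = 0.40, unknown = 0.15),
    age_mix = c(under18 = 0.08, a18_44 = 0.42, a45_64 = 0.33,
                a65_plus = 0.17),
    missing_age_rate = 0.2,
    serious_rate = 0.1,
    events_mean = 1.7,
    events_disp = 1.0,
    reporter_mix = c(CN = 0.35, MD = 0.25, PH = 0.1, OT = 0.2, none = 0.1),
    indication_rate = 0.7
  )
}

#' Configuration for the synthetic report generator
#'
#' Describes a synthetic spontaneous-report database: a background
#' multinomial over (drug, preferred term) with implanted drug-event pairs
#' whose joint probability is multiplied by `rho` (then globally
#' renormalized, so `rho` is interpretable as a relative reporting ratio),
#' plus Table-1-like demographic structure, duplicate/follow-up versions
#' and missingness.
#'
#' @param seed integer seed; the generator is fully reproducible from it.
#' @param n_reports number of base reports (before duplicate versions).
#' @param n_drugs,n_pts,n_socs vocabulary sizes.
#' @param target_drugs list of target-drug specs; each a list with `name`,
#'   optional `synonyms`, `share` (marginal report probability), and any
#'   demographic overrides of the background profile (`sex_mix`,
#'   `age_mix`, `missing_age_rate`, `serious_rate`, `events_mean`,
#'   `events_disp`, `reporter_mix`, `indication_rate`).
#' @param indication_pt indication preferred term attached to target-drug
#'   suspect entries (at each target's `indication_rate`).
#' @param implanted data frame with columns `drug`, `pt`, `rho` (> 0).
#' @param duplicate_rate probability a case gets an extra same-date
#'   version; `followup_rate` probability of an extra later-dated version.
#' @param orphan_rate fraction of reports contributing an extra REAC row
#'   with an unknown primaryid (default 0).
#' @param event_date_rate,therapy_date_rate,negative_onset_rate
#'   availability of event dates, therapy start dates, and the rate at
#'   which an (implausible) negative onset interval is injected.
#' @param weight_present_rate availability of body weight.
#' @param date_range character vector of two dates bounding report dates.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(seed = 1, n_reports = 10000, n_drugs = 25,
                         n_pts = 250, n_socs = 27,
                         target_drugs = list(list(name = "baricitinib",
                                                  synonyms = "olumiant",
                                                  share = 0.04)),
                         indication_pt = "Alopecia areata",
                         implanted = data.frame(drug = character(),
                                                pt = character(),
                                                rho = double()),
                         duplicate_rate = 0.03, followup_rate = 0.03,
                         orphan_rate = 0,
                         event_date_rate = 0.9, therapy_date_rate = 0.09,
                         negative_onset_rate = 0.01,
                         weight_present_rate = 0.1,
                         date_range = c("2021-01-01", "2024-03-31"),
                         ...) {
  profile <- modifyList(.default_profile(), list(...))
  cfg <- list(
    seed = seed, n_reports = n_reports, n_drugs = n_drugs, n_pts = n_pts,
    n_socs = n_socs, target_drugs = target_drugs,
    indication_pt = indication_pt, implanted = as_tibble(implanted),
    duplicate_rate = duplicate_rate, followup_rate = followup_rate,
    orphan_rate = orphan_rate, event_date_rate = event_date_rate,
    therapy_date_rate = therapy_date_rate,
    negative_onset_rate = negative_onset_rate,
    weight_present_rate = weight_present_rate,
    date_range = as.Date(date_range), profile = profile
  )
  rates <- c(duplicate_rate, followup_rate, orphan_rate, event_date_rate,
             therapy_date_rate, negative_onset_rate, weight_present_rate)
  if (any(rates < 0 | rates > 1)) {
    pv_validation_error("all rates must lie in [0, 1]")
  }
  if (nrow(cfg$implanted) > 0 && any(cfg$implanted$rho <= 0)) {
    pv_validation_error("implanted multipliers rho must be > 0")
  }
  shares <- vapply(target_drugs, function(t) t$share, numeric(1))
  if (sum(shares) >= 1) {
    pv_validation_error("target drug shares must sum to less than 1")
  }
  if (length(target_drugs) > n_drugs) {
    pv_validation_error("more target drugs than the drug vocabulary size")
  }
  pt_vocab <- sprintf("PT_%04d", seq_len(n_pts))
  if (nrow(cfg$implanted) > 0) {
    bad <- !(cfg$implanted$pt %in% pt_vocab) |
      !(cfg$implanted$drug %in% vapply(target_drugs, `[[`, "", "name"))
    if (any(bad)) {
      pv_validation_error(
        "implanted pairs must reference target drugs and in-vocabulary PTs"
      )
    }
  }
  structure(cfg, class = "synth_config")
}

sample_mix <- function(n, mix) {
  sample(names(mix), n, replace = TRUE, prob = mix)
}

#' Generate a synthetic spontaneous-report database
#'
#' Draws `n_reports` reports from the configured background (drug, PT)
#' multinomial with implanted multipliers, attaches demographics, outcome,
#' therapy and indication records, emits duplicate/follow-up versions
#' (extra versions share `caseid`, increment `primaryid` and carry
#' equal-or-later dates), and splits everything into quarterly bundles.
#'
#' @param config a [synth_config()].
#' @return list with elements `bundles` (list of `faers_bundle`), `dict`
#'   (the PT dictionary) and `truth`, a ground-truth list carrying per-case
#'   lineage (`duplicates_removed`), the implanted multiplier table, the
#'   per-target cohort ids and sizes, and the pre-masking demographics.
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  n <- config$n_reports
  dict <- synth_dictionary(config$n_pts, config$n_socs, config$seed)
  pt_vocab <- dict$pt
  targets <- config$target_drugs
  target_names <- vapply(targets, `[[`, "", "name")
  n_bg_drugs <- config$n_drugs - length(targets)
  drug_vocab <- c(target_names, sprintf("drug_%03d", seq_len(n_bg_drugs)))

  # background joint distribution over (drug, pt) with implantation
  shares <- vapply(targets, `[[`, 1, "share")
  p_drug <- c(shares, rep((1 - sum(shares)) / n_bg_drugs, n_bg_drugs))
  w_pt <- seq(2, 0.5, length.out = config$n_pts)
  p_pt <- w_pt / sum(w_pt)
  joint <- outer(p_drug, p_pt)
  if (nrow(config$implanted) > 0) {
    di <- match(config$implanted$drug, drug_vocab)
    pj <- match(config$implanted$pt, pt_vocab)
    extra <- sum(joint[cbind(di, pj)] * (config$implanted$rho - 1))
    if (extra + 1 <= 0 || sum(joint[cbind(di, pj)] * config$implanted$rho) >= 1) {
      pv_validation_error("implanted mass after multiplication is infeasible")
    }
    joint[cbind(di, pj)] <- joint[cbind(di, pj)] * config$implanted$rho
  }
  joint <- joint / sum(joint)
  drug_marg <- rowSums(joint)

  drug_idx <- sample.int(config$n_drugs, n, replace = TRUE, prob = drug_marg)
  is_target <- drug_idx <= length(targets)

  # per-report demographic profile (background default, target overrides)
  prof_of <- function(ti) {
    if (ti == 0) return(config$profile)
    modifyList(config$profile, targets[[ti]][setdiff(names(targets[[ti]]),
                                                     c("name", "synonyms",
                                                       "share"))])
  }
  group <- ifelse(is_target, drug_idx, 0L)
  sex <- character(n); band <- character(n); miss_age <- logical(n)
  serious <- logical(n); ev_mean <- numeric(n); ev_disp <- numeric(n)
  occp <- character(n); has_ind <- logical(n)
  for (g in unique(group)) {
    idx <- which(group == g); p <- prof_of(g)
    sex[idx] <- sample_mix(length(idx), p$sex_mix)
    band[idx] <- sample_mix(length(idx), p$age_mix)
    miss_age[idx] <- runif(length(idx)) < p$missing_age_rate
    serious[idx] <- runif(length(idx)) < p$serious_rate
    ev_mean[idx] <- p$events_mean
    ev_disp[idx] <- p$events_disp
    occp[idx] <- sample_mix(length(idx), p$reporter_mix)
    has_ind[idx] <- runif(length(idx)) < p$indication_rate
  }
  true_age <- numeric(n)
  rng <- list(under18 = c(6, 17.9), a18_44 = c(18, 44.9),
              a45_64 = c(45, 64.9), a65_plus = c(65, 89))
  for (b in names(rng)) {
    idx <- which(band == b)
    true_age[idx] <- runif(length(idx), rng[[b]][1], rng[[b]][2])
  }
  true_age <- round(true_age, 1)

  # events: k per report (shifted negative binomial, min 1), PTs drawn from
  # the drug-conditional distribution
  k <- 1L + rnbinom(n, size = ev_disp, mu = pmax(ev_mean - 1, 1e-6))
  ev_report <- integer(0); ev_pt <- character(0)
  for (d in sort(unique(drug_idx))) {
    idx <- which(drug_idx == d)
    tot <- sum(k[idx])
    pts <- sample.int(config$n_pts, tot, replace = TRUE,
                      prob = joint[d, ] / drug_marg[d])
    ev_report <- c(ev_report, rep(idx, k[idx]))
    ev_pt <- c(ev_pt, pt_vocab[pts])
  }
  ev_ord <- order(ev_report)
  events <- tibble(report = ev_report[ev_ord], pt = ev_pt[ev_ord])

  # dates
  d0 <- as.integer(config$date_range[1]); d1 <- as.integer(config$date_range[2])
  fda_dt <- as.Date(sample(d0:d1, n, replace = TRUE), origin = "1970-01-01")
  has_event_dt <- runif(n) < config$event_date_rate
  event_dt <- fda_dt - pmin(round(rexp(n, 1 / 60)), 900)
  event_dt[!has_event_dt] <- NA
  has_ther <- (runif(n) < config$therapy_date_rate) & has_event_dt
  onset <- pmin(round(rexp(n, 1 / 100)), 1500)
  neg <- runif(n) < config$negative_onset_rate
  onset[neg] <- -sample(1:30, sum(neg), replace = TRUE)
  start_dt <- event_dt - onset
  start_dt[!has_ther] <- NA

  # outcomes for serious reports
  outc_codes <- c("OT", "HO", "LT", "DE", "DS", "RI", "CA")
  outc_prob <- c(0.75, 0.12, 0.03, 0.04, 0.02, 0.02, 0.02)
  n_outc <- ifelse(serious, 1L + (runif(n) < 0.05), 0L)
  outc <- tibble(
    report = rep(seq_len(n), n_outc),
    code = sample(outc_codes, sum(n_outc), replace = TRUE, prob = outc_prob)
  ) |> distinct()

  # indications: targets use the study indication, background drugs others
  other_ind <- c("Rheumatoid arthritis", "Psoriasis", "Atopic dermatitis",
                 "Ulcerative colitis")
  indication <- ifelse(is_target & has_ind, config$indication_pt,
                       ifelse(has_ind, sample(other_ind, n, replace = TRUE),
                              NA_character_))

  # raw drug-name variants exercise standardization (case, padding,
  # synonyms for targets)
  raw_name <- drug_vocab[drug_idx]
  for (ti in seq_along(targets)) {
    idx <- which(drug_idx == ti)
    forms <- c(targets[[ti]]$name, targets[[ti]]$synonyms %||% character(0))
    nm <- sample(forms, length(idx), replace = TRUE)
    style <- sample(3, length(idx), replace = TRUE)
    nm <- ifelse(style == 1, nm, ifelse(style == 2, toupper(nm),
                                        paste0(" ", nm, " ")))
    raw_name[idx] <- nm
  }
  role <- ifelse(runif(n) < 0.9, "PS", "SS")
  has_conc <- runif(n) < 0.3
  conc_name <- drug_vocab[sample.int(config$n_drugs, n, replace = TRUE,
                                     prob = drug_marg)]

  caseid <- as.character(2000000L + seq_len(n))

  # versions: 1 = base; duplicates share the date, follow-ups are later
  dup <- runif(n) < config$duplicate_rate
  fup <- runif(n) < config$followup_rate
  fup_offset <- sample(1:90, n, replace = TRUE)
  versions <- tibble(report = seq_len(n), version = 1L,
                     fda = fda_dt)
  if (any(dup)) {
    versions <- bind_rows(versions, tibble(report = which(dup), version = 2L,
                                           fda = fda_dt[dup]))
  }
  if (any(fup)) {
    versions <- bind_rows(versions,
                          tibble(report = which(fup),
                                 version = 2L + dup[fup],
                                 fda = fda_dt[fup] + fup_offset[fup]))
  }
  versions <- arrange(versions, .data$report, .data$version)
  versions$primaryid <- paste0(caseid[versions$report], versions$version)

  # DEMO payload (age encoded in mixed units; masked values become "")
  age_unit <- sample(c("YR", "MON", "DY"), n, replace = TRUE,
                     prob = c(0.9, 0.07, 0.03))
  age_val <- ifelse(age_unit == "YR", round(true_age),
                    ifelse(age_unit == "MON", round(true_age * 12),
                           round(true_age * 365.25)))
  age_str <- ifelse(miss_age, "", as.character(age_val))
  age_cod <- ifelse(miss_age, "", age_unit)
  wt_present <- runif(n) < config$weight_present_rate
  wt <- round(pmin(pmax(rnorm(n, 66, 16), 35), 125), 1)
  countries <- c("US", "JP", "DE", "FR", "CA")
  occr <- sample(countries, n, replace = TRUE,
                 prob = c(0.85, 0.05, 0.04, 0.03, 0.03))

  r <- versions$report
  demo <- tibble(
    primaryid = versions$primaryid,
    caseid = caseid[r],
    caseversion = as.character(versions$version),
    fda_dt = format_faers_date(versions$fda),
    event_dt = format_faers_date(event_dt[r]),
    age = age_str[r],
    age_cod = age_cod[r],
    sex = ifelse(sex[r] == "unknown", "", sex[r]),
    wt = ifelse(wt_present[r], as.character(wt[r]), ""),
    wt_cod = ifelse(wt_present[r], "KG", ""),
    occp_cod = ifelse(occp[r] == "none", "", occp[r]),
    occr_country = occr[r],
    reporter_country = occr[r]
  )

  per_version <- function(tbl) {
    # replicate per-report rows for every version of that report
    merged <- inner_join(versions, tbl, by = "report",
                         relationship = "many-to-many")
    merged
  }
  drug_tbl <- bind_rows(
    tibble(report = seq_len(n), drug_seq = "1", role_cod = role,
           drugname = raw_name),
    tibble(report = which(has_conc), drug_seq = "2", role_cod = "C",
           drugname = conc_name[has_conc])
  )
  drug_out <- per_version(drug_tbl) |>
    transmute(.data$primaryid, caseid = caseid[.data$report],
              .data$drug_seq, .data$role_cod, .data$drugname)

  reac_out <- per_version(events) |>
    transmute(.data$primaryid, caseid = caseid[.data$report], .data$pt)
  if (config$orphan_rate > 0) {
    n_orph <- round(config$orphan_rate * n)
    reac_out <- bind_rows(reac_out, tibble(
      primaryid = paste0("99", sample(1e6, n_orph)),
      caseid = paste0("99", sample(1e6, n_orph)),
      pt = sample(pt_vocab, n_orph, replace = TRUE)
    ))
  } else {
    n_orph <- 0L
  }

  outc_out <- per_version(outc) |>
    transmute(.data$primaryid, caseid = caseid[.data$report],
              outc_cod = .data$code)
  ther_tbl <- tibble(report = which(has_ther), dsg_drug_seq = "1",
                     start_dt = format_faers_date(start_dt[has_ther]),
                     end_dt = "")
  ther_out <- per_version(ther_tbl) |>
    transmute(.data$primaryid, caseid = caseid[.data$report],
              .data$dsg_drug_seq, .data$start_dt, .data$end_dt)
  indi_tbl <- tibble(report = which(!is.na(indication)),
                     indi_drug_seq = "1",
                     indi_pt = indication[!is.na(indication)])
  indi_out <- per_version(indi_tbl) |>
    transmute(.data$primaryid, caseid = caseid[.data$report],
              .data$indi_drug_seq, .data$indi_pt)
  rpsr_has <- runif(n) < 0.5
  rpsr_tbl <- tibble(report = which(rpsr_has),
                     rpsr_cod = sample(c("FGN", "HP", "CSM", "OTH"),
                                       sum(rpsr_has), replace = TRUE))
  rpsr_out <- per_version(rpsr_tbl) |>
    transmute(.data$primaryid, caseid = caseid[.data$report],
              .data$rpsr_cod)

  # quarterly split keyed on each version's report date
  qlabel <- paste0(format(versions$fda, "%Y"), "Q",
                   (as.integer(format(versions$fda, "%m")) - 1) %/% 3 + 1)
  pid_quarter <- setNames(qlabel, versions$primaryid)
  split_tbl <- function(tbl) {
    q <- unname(pid_quarter[tbl$primaryid])
    q[is.na(q)] <- sort(unique(qlabel))[1]   # orphans land in the first quarter
    split(tbl, q)
  }
  tabs <- list(DEMO = demo, DRUG = drug_out, REAC = reac_out,
               OUTC = outc_out, THER = ther_out, INDI = indi_out,
               RPSR = rpsr_out)
  by_q <- lapply(tabs, split_tbl)
  quarters <- sort(unique(qlabel))
  bundles <- lapply(quarters, function(q) {
    faers_bundle(lapply(names(tabs), function(kind) {
      piece <- by_q[[kind]][[q]]
      if (is.null(piece)) piece <- tabs[[kind]][0, , drop = FALSE]
      arrange(piece, .data$primaryid)
    }) |> setNames(names(tabs)), q)
  })

  cohort_ids <- lapply(seq_along(targets), function(ti) {
    keep <- drug_idx == ti & !is.na(indication) &
      indication == config$indication_pt
    # id of the version that deduplication retains (latest date, then
    # greatest primaryid)
    vv <- versions[versions$report %in% which(keep), , drop = FALSE]
    vv <- vv[order(vv$report, vv$fda, vv$version), , drop = FALSE]
    vv$primaryid[!duplicated(vv$report, fromLast = TRUE)]
  })
  names(cohort_ids) <- target_names

  truth <- list(
    n_reports = n,
    duplicates_removed = sum(dup) + sum(fup),
    n_orphans = n_orph,
    implanted = config$implanted,
    cohort_ids = cohort_ids,
    cohort_sizes = lengths(cohort_ids),
    demographics = tibble(caseid = caseid, drug = drug_vocab[drug_idx],
                          true_age = true_age, sex = sex,
                          serious = serious, n_events = k,
                          indication = indication),
    lineage = versions |> count(.data$report, name = "n_versions")
  )
  list(bundles = bundles, dict = dict, truth = truth)
}

#' Write synthetic bundles to a quarterly file layout
#'
#' @param bundles list of `faers_bundle` objects.
#' @param dir output directory (created if needed).
#' @param delim field delimiter.
#' @return `dir`, invisibly.
#' @export
synth_write <- function(bundles, dir, delim = "$") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in bundles) {
    for (kind in names(b$tables)) {
      faers_write_table(b$tables[[kind]],
                        file.path(dir, paste0(tolower(kind), "_", b$quarter,
                                              ".txt")),
                        delim = delim)
    }
  }
  invisible(dir)
}

#' Paper-shaped two-drug study scenario
#'
#' A canned configuration emulating the demographic structure of a
#' two-JAK-inhibitor alopecia-areata report study: a recently approved
#' drug (consumer-heavy reporting, ~52% missing age, ~15% serious, ~1.7
#' events per report) against an older off-label comparator
#' (professional-heavy reporting, ~10% missing age, ~11% serious, ~3
#' events per report), sex mix about 60/25/15, cohort shares sized to
#' yield roughly 550 and 648 reports at the default database size.
#'
#' @param seed integer seed.
#' @param n_reports total database size.
#' @return a `synth_config`.
#' @export
synth_scenario_aa <- function(seed = 1, n_reports = 5000) {
  synth_config(
    seed = seed, n_reports = n_reports, n_drugs = 25, n_pts = 250,
    target_drugs = list(
      list(name = "baricitinib", synonyms = "olumiant", share = 0.11,
           sex_mix = c(F = 0.60, M = 0.25, unknown = 0.15),
           age_mix = c(under18 = 0.034, a18_44 = 0.555, a45_64 = 0.332,
                       a65_plus = 0.079),
           missing_age_rate = 0.518, serious_rate = 0.1545,
           events_mean = 1.7, events_disp = 1.2,
           reporter_mix = c(CN = 0.69, MD = 0.045, PH = 0.087, OT = 0.0,
                            none = 0.178),
           indication_rate = 1),
      list(name = "tofacitinib", synonyms = c("xeljanz", "xeljanz xr"),
           share = 0.1296,
           sex_mix = c(F = 0.63, M = 0.32, unknown = 0.05),
           age_mix = c(under18 = 0.245, a18_44 = 0.443, a45_64 = 0.250,
                       a65_plus = 0.062),
           missing_age_rate = 0.099, serious_rate = 0.1111,
           events_mean = 3.0, events_disp = 1.2,
           reporter_mix = c(CN = 0.26, MD = 0.18, PH = 0.083, OT = 0.47,
                            none = 0.007),
           indication_rate = 1)
    ),
    implanted = data.frame(
      drug = c("baricitinib", "baricitinib", "tofacitinib", "tofacitinib"),
      pt = c("PT_0015", "PT_0040", "PT_0090", "PT_0120"),
      rho = c(6, 6, 6, 6)
    )
  )
}

#' Signal-recovery benchmark scenario
#'
#' A single-target configuration for parameter-recovery experiments: a
#' large database with five implanted drug-event pairs at a known
#' reporting multiplier against at least 200 background terms.
#'
#' @param seed integer seed.
#' @param n_reports database size (default 50,000).
#' @param rho implanted reporting multiplier (default 8).
#' @return a `synth_config`; the implanted pairs are recorded in
#'   `$implanted`.
#' @export
synth_scenario_signal <- function(seed = 1, n_reports = 50000, rho = 8) {
  pts <- sprintf("PT_%04d", c(10, 60, 110, 160, 210))
  synth_config(
    seed = seed, n_reports = n_reports, n_drugs = 25, n_pts = 250,
    target_drugs = list(list(name = "baricitinib", synonyms = "olumiant",
                             share = 0.04, indication_rate = 1)),
    implanted = data.frame(drug = "baricitinib", pt = pts, rho = rho)
  )
}
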