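test_that("contingency construction counts at report level", {
  cohort <- mk_cases(10, events = rep(list("PT_X"), 10))
  extra <- mk_cases(990, primaryid = as.character(5000 + 1:990),
                    caseid = as.character(5000 + 1:990),
                    events = c(rep(list(c("PT_X", "PT_X")), 20),
                               rep(list("PT_Y"), 970)))
  background <- dplyr::bind_rows(cohort, extra)
  t <- build_contingency(cohort, background, "PT_X")
  expect_equal(c(t$a, t$b, t$c, t$d), c(10, 0, 20, 970))

  none <- build_contingency(cohort, background, "PT_ABSENT")
  expect_equal(c(none$a, none$c), c(0, 0))

  expect_error(build_contingency(extra, cohort, "PT_X"),
               class = "pv_data_error")
})

test_that("screens are deterministic and order-invariant", {
  set.seed(77)
  pts <- paste0("PT_", sprintf("%03d", 1:40))
  n <- 400
  cases <- mk_cases(n,
    drug_canonical = c(rep(list("drugx"), 80), rep(list("other"), n - 80)),
    events = lapply(1:n, function(i) sample(pts, sample(1:3, 1))))
  cohort <- select_cohort(cases, "drugx")
  s1 <- run_screen(cohort, cases, min_a = 1)
  perm <- sample(n)
  s2 <- run_screen(select_cohort(cases[perm, ], "drugx"), cases[perm, ],
                   min_a = 1)
  expect_equal(as.data.frame(tidy(s1)), as.data.frame(tidy(s2)))
  # empty cohort gives an empty, well-formed result
  s0 <- run_screen(cohort[0, ], cases)
  expect_s3_class(s0, "pv_screen")
  expect_equal(nrow(s0), 0)
})

test_that("ranking keys order and tie-break as documented", {
  set.seed(12)
  pts <- paste0("PT_", sprintf("%03d", 1:30))
  n <- 300
  cases <- mk_cases(n,
    drug_canonical = c(rep(list("drugx"), 60), rep(list("other"), n - 60)),
    events = lapply(1:n, function(i) sample(pts, 2)))
  s <- run_screen(select_cohort(cases, "drugx"), cases, min_a = 1)
  top <- rank_top(s, 5)
  expect_equal(nrow(top), 5)
  expect_true(all(diff(top$a) <= 0))
  ties <- top$pt[top$a == top$a[1]]
  expect_equal(ties, sort(ties))
  expect_equal(nrow(rank_top(s, 10^6)), nrow(s))
  strength <- rank_top(s, nrow(s), key = "strength")
  expect_true(all(diff(strength$ebgm) <= 1e-12))
})

test_that("subgroup strata partition the cohort counts", {
  set.seed(5)
  n <- 600
  pts <- paste0("PT_", sprintf("%02d", 1:15))
  cases <- mk_cases(n,
    sex = sample(c("F", "M", "unknown"), n, TRUE, prob = c(.5, .4, .1)),
    age_years = ifelse(runif(n) < 0.2, NA, runif(n, 5, 90)),
    serious = runif(n) < 0.3,
    drug_canonical = c(rep(list("drugx"), 150), rep(list("other"), n - 150)),
    events = lapply(1:n, function(i) sample(pts, sample(1:2, 1))))
  cohort <- select_cohort(cases, "drugx")
  whole <- run_screen(cohort, cases, min_a = 1)
  for (axis in c("gender", "age_band", "seriousness")) {
    sg <- subgroup_screen(cohort, cases, axis = axis, min_a = 1,
                          min_cases = 1)
    per_level <- dplyr::bind_rows(lapply(sg, tidy))
    agg <- per_level |> dplyr::group_by(pt) |>
      dplyr::summarise(a = sum(a), .groups = "drop")
    merged <- dplyr::left_join(tidy(whole), agg, by = "pt",
                               suffix = c("_whole", "_sum"))
    expect_equal(merged$a_sum, merged$a_whole)
  }
})

test_that("small strata are skipped with a marker", {
  cases <- mk_cases(30, sex = c(rep("F", 28), "M", "unknown"))
  sg <- subgroup_screen(cases, cases, axis = "gender", min_cases = 5)
  expect_s3_class(sg$M, "pv_screen_skipped")
  expect_equal(sg$M$n, 1)
  expect_s3_class(sg$F, "pv_screen")
})

test_that("a stratum-specific signal is flagged only in its stratum", {
  set.seed(91)
  n_bg <- 4000
  pts <- paste0("PT_", sprintf("%03d", 1:50))
  mk_arm <- function(n, sex, enrich, offset) {
    evs <- lapply(seq_len(n), function(i) {
      base <- sample(pts[-1], sample(1:2, 1))
      if (enrich && runif(1) < 0.25) c(base, "PT_001") else base
    })
    mk_cases(n, primaryid = as.character(offset + 1:n),
             caseid = as.character(offset + 1:n),
             sex = rep(sex, n), events = evs)
  }
  # female cohort carries the enriched term; male cohort does not
  coh_f <- mk_arm(150, "F", TRUE, 10000)
  coh_m <- mk_arm(150, "M", FALSE, 20000)
  bg_f <- mk_arm(n_bg / 2, "F", FALSE, 30000)
  bg_m <- mk_arm(n_bg / 2, "M", FALSE, 40000)
  bg_f$drug_canonical <- rep(list("other"), nrow(bg_f))
  bg_m$drug_canonical <- rep(list("other"), nrow(bg_m))
  cohort <- dplyr::bind_rows(coh_f, coh_m)
  background <- dplyr::bind_rows(cohort, bg_f, bg_m)
  sg <- subgroup_screen(cohort, background, axis = "gender", min_cases = 10)
  f_row <- tidy(sg$F) |> dplyr::filter(pt == "PT_001")
  m_row <- tidy(sg$M) |> dplyr::filter(pt == "PT_001")
  expect_true(f_row$flag_ror && f_row$flag_bcpnn)
  expect_true(nrow(m_row) == 0 || !m_row$flag_any)
})

test_that("heatmap matrices union top terms and round-trip through text", {
  set.seed(8)
  n <- 500
  pts <- paste0("PT_", sprintf("%02d", 1:20))
  cases <- mk_cases(n,
    sex = sample(c("F", "M"), n, TRUE),
    drug_canonical = c(rep(list("drugx"), 120), rep(list("other"), n - 120)),
    events = lapply(1:n, function(i) sample(pts, 2)))
  cohort <- select_cohort(cases, "drugx")
  sg <- subgroup_screen(cohort, cases, axis = "gender", min_a = 2,
                        min_cases = 5)
  hm <- heatmap_matrix(sg, top_k = 5)
  expect_true(all(c("pt", "F", "M") %in% names(hm)))
  union_pts <- sort(unique(c(rank_top(sg$F, 5)$pt, rank_top(sg$M, 5)$pt)))
  expect_equal(hm$pt, union_pts)
  # a term screened in one stratum only is missing in the other
  only_f <- setdiff(tidy(sg$F)$pt, tidy(sg$M)$pt)
  if (length(only_f) > 0 && only_f[1] %in% hm$pt) {
    expect_true(is.na(hm$M[hm$pt == only_f[1]]))
  }
  f <- withr::local_tempfile()
  write_heatmap_matrix(hm, f)
  back <- read_heatmap_matrix(f)
  expect_equal(back$values$pt, hm$pt)
  expect_equal(back$values$F, hm$F)
  expect_equal(back$counts$M, attr(hm, "counts")$M)

  # single stratum: the matrix is that stratum's top-k column
  hm1 <- heatmap_matrix(sg[1], top_k = 5)
  expect_equal(sort(hm1$pt), sort(rank_top(sg$F, 5)$pt))
})
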