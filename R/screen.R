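# report-level event flags: one row per (primaryid, distinct pt)
report_pt_pairs <- function(cases) {
  flatten_listcol(cases$primaryid, cases$events, "pt") |>
    mutate(pt = trimws(.data$pt)) |>
    distinct(.data$primaryid, .data$pt)
}

#' Build the 2x2 table for one preferred term
#'
#' Report-level counting against a background that contains the cohort:
#' `a` cohort reports listing the term, `b` cohort reports not listing it,
#' `c` non-cohort background reports listing it, `d` the remainder.  A
#' report counts once per term no matter how often the term repeats.
#'
#' @param cohort cohort case tibble.
#' @param background background case tibble; must contain every cohort
#'   `primaryid`.
#' @param pt preferred term.
#' @return one-row contingency tibble (see [contingency_table()]) with a
#'   `pt` column.
#' @export
build_contingency <- function(cohort, background, pt) {
  check_cohort_subset(cohort, background)
  coh <- report_pt_pairs(cohort)
  bg <- report_pt_pairs(background)
  a <- sum(coh$pt == pt)
  tot <- sum(bg$pt == pt)
  n_coh <- nrow(cohort); n_bg <- nrow(background)
  bind_cols(pt = pt,
            contingency_table(a, n_coh - a, tot - a, n_bg - n_coh - (tot - a)))
}

check_cohort_subset <- function(cohort, background) {
  if (!all(cohort$primaryid %in% background$primaryid)) {
    pv_data_error("the cohort must be a subset of the background reports")
  }
}

#' Run the four-algorithm disproportionality screen
#'
#' One row per preferred term reported at least `min_a` times in the
#' cohort, with all four estimators and their signal flags.  The shrinker
#' prior is fitted once, on all cells with a >= 1, for stability, and the
#' same prior scores every screened row.  Deterministic given its inputs
#' and invariant to the ordering of the input cases.
#'
#' @param cohort cohort case tibble.
#' @param background background case tibble containing the cohort.  The
#'   default comparator is the full cleaned database; pass a
#'   within-indication subset for an indication-restricted comparator.
#' @param dict optional `meddra_dict` used to attach a `soc` column (terms
#'   missing from it raise an error).
#' @param thresholds a [signal_thresholds()] object.
#' @param min_a minimum cohort report count for a term to be screened.
#' @param comparator_mode label recorded in the result
#'   (`"full_database"` or `"within_indication"`).
#' @return a `pv_screen`: tibble of screened rows sorted by descending `a`
#'   (ties alphabetical by term), with attributes `cohort_size`,
#'   `background_size`, `thresholds`, `prior`, `comparator_mode`.
#' @export
run_screen <- function(cohort, background, dict = NULL,
                       thresholds = signal_thresholds(), min_a = 3,
                       comparator_mode = "full_database") {
  if (min_a < 1) pv_validation_error("`min_a` must be at least 1")
  check_cohort_subset(cohort, background)
  n_coh <- nrow(cohort); n_bg <- nrow(background)

  empty <- tibble(pt = character(), soc = character(), a = integer(),
                  b = integer(), c = integer(), d = integer(),
                  n = integer(), expected = double())
  if (n_coh == 0) {
    return(new_pv_screen(empty, n_coh, n_bg, thresholds, NULL,
                         comparator_mode))
  }

  coh_pairs <- report_pt_pairs(cohort)
  in_cohort <- background$primaryid %in% cohort$primaryid
  bg_pairs <- report_pt_pairs(background[!in_cohort, , drop = FALSE])

  counts <- full_join(
    count(coh_pairs, .data$pt, name = "a"),
    count(bg_pairs, .data$pt, name = "c"),
    by = "pt"
  ) |>
    mutate(a = coalesce(.data$a, 0L), c = coalesce(.data$c, 0L)) |>
    arrange(.data$pt)

  cells <- bind_cols(
    pt = counts$pt,
    contingency_table(counts$a, n_coh - counts$a, counts$c,
                      n_bg - n_coh - counts$c)
  )
  prior <- gps_fit_prior(cells$a[cells$a >= 1],
                         cells$expected[cells$a >= 1])

  rows <- cells |> filter(.data$a >= min_a)
  if (nrow(rows) == 0) {
    return(new_pv_screen(empty, n_coh, n_bg, thresholds, prior,
                         comparator_mode))
  }
  rows <- signal_metrics(rows, prior = prior, thresholds = thresholds)
  if (!is.null(dict)) {
    miss <- setdiff(rows$pt, dict$pt)
    if (length(miss) > 0) {
      pv_data_error(paste0("screened term(s) missing from the dictionary: ",
                           paste(head(miss, 10), collapse = ", ")))
    }
    rows <- mutate(rows, soc = dict$soc[match(.data$pt, dict$pt)],
                   .after = "pt")
  }
  rows <- arrange(rows, desc(.data$a), .data$pt)
  new_pv_screen(rows, n_coh, n_bg, thresholds, prior, comparator_mode)
}

new_pv_screen <- function(rows, cohort_size, background_size, thresholds,
                          prior, comparator_mode) {
  structure(
    rows,
    cohort_size = cohort_size,
    background_size = background_size,
    thresholds = thresholds,
    prior = prior,
    comparator_mode = comparator_mode,
    class = c("pv_screen", class(rows))
  )
}

#' @export
print.pv_screen <- function(x, ...) {
  cat("<pv_screen> ", nrow(x), " screened terms; cohort ",
      attr(x, "cohort_size"), " of ", attr(x, "background_size"),
      " reports (", attr(x, "comparator_mode"), ")\n", sep = "")
  NextMethod()
}

#' Rank the top terms of a screen
#'
#' @param result a `pv_screen`.
#' @param k number of rows to keep (capped at the row count).
#' @param key `"frequency"` (by report count `a`), `"signal_count"` (by
#'   number of positive flags, then `a`), or `"strength"` (by EBGM, then
#'   ROR).  Ties always break alphabetically by term.
#' @return the top rows as a tibble, in rank order.
#' @export
rank_top <- function(result, k = 30,
                     key = c("frequency", "signal_count", "strength")) {
  key <- match.arg(key)
  rows <- as_tibble(result)
  if (nrow(rows) == 0) return(rows)
  ord <- switch(key,
    frequency = order(-rows$a, rows$pt),
    signal_count = {
      nf <- rows$flag_ror + rows$flag_prr + rows$flag_bcpnn + rows$flag_mgps
      order(-nf, -rows$a, rows$pt)
    },
    strength = order(-rows$ebgm, -rows$ror, rows$pt)
  )
  rows[head(ord, k), , drop = FALSE]
}

#' Stratified subgroup screens
#'
#' Runs the screen within each level of a demographic axis, restricting
#' the cohort and the background to the same stratum so that reporting
#' imbalances across strata cannot masquerade as drug signals.  Strata
#' with fewer cohort reports than `min_cases` are emitted as skipped
#' markers.
#'
#' @param cohort,background case tibbles (cohort a subset of background).
#' @param axis `"gender"`, `"age_band"` or `"seriousness"`.
#' @param dict,thresholds,min_a passed to [run_screen()].
#' @param min_cases minimum cohort size for a stratum to be screened.
#' @return a `pv_subgroups`: named list of `pv_screen` objects (or
#'   `pv_screen_skipped` markers), one per stratum level, with attribute
#'   `axis`.
#' @export
subgroup_screen <- function(cohort, background,
                            axis = c("gender", "age_band", "seriousness"),
                            dict = NULL, thresholds = signal_thresholds(),
                            min_a = 3, min_cases = 10) {
  axis <- match.arg(axis)
  check_cohort_subset(cohort, background)
  strat <- function(cases) {
    switch(axis,
      gender = factor(cases$sex, levels = c("F", "M", "unknown")),
      age_band = age_band(cases$age_years),
      seriousness = factor(ifelse(cases$serious, "serious", "non_serious"),
                           levels = c("serious", "non_serious"))
    )
  }
  coh_lv <- strat(cohort); bg_lv <- strat(background)
  out <- lapply(levels(coh_lv), function(lv) {
    coh_i <- cohort[!is.na(coh_lv) & coh_lv == lv, , drop = FALSE]
    if (nrow(coh_i) < min_cases) {
      return(structure(list(level = lv, n = nrow(coh_i)),
                       class = "pv_screen_skipped"))
    }
    bg_i <- background[!is.na(bg_lv) & bg_lv == lv, , drop = FALSE]
    run_screen(coh_i, bg_i, dict = dict, thresholds = thresholds,
               min_a = min_a)
  })
  names(out) <- levels(coh_lv)
  structure(out, axis = axis, class = "pv_subgroups")
}

#' @export
print.pv_screen_skipped <- function(x, ...) {
  cat("<skipped stratum '", x$level, "': ", x$n, " cohort reports>\n",
      sep = "")
  invisible(x)
}

#' @export
print.pv_subgroups <- function(x, ...) {
  cat("<pv_subgroups axis=", attr(x, "axis"), "> levels: ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Term-by-stratum heatmap matrix
#'
#' Builds the plot-ready matrix behind subgroup heatmaps: rows are the
#' union of each stratum's top-k terms (ranked by report count), columns
#' are strata, cells carry the chosen metric (`NA` where the term was not
#' screened in that stratum).  The companion report-count matrix is
#' attached as an attribute.
#'
#' @param results a `pv_subgroups` (skipped strata contribute nothing).
#' @param top_k how many top terms per stratum enter the row union.
#' @param metric column of the screen rows to display (default `"ic"`).
#' @return a `pv_heatmap`: tibble with column `pt` plus one column per
#'   stratum, attributes `counts` (matching count tibble) and `metric`.
#' @export
heatmap_matrix <- function(results, top_k = 30, metric = "ic") {
  screens <- results[!vapply(results, inherits, logical(1),
                             "pv_screen_skipped")]
  if (length(screens) == 0) {
    pv_data_error("no screened strata to build a heatmap from")
  }
  pts <- sort(unique(unlist(lapply(screens, function(s)
    rank_top(s, top_k, "frequency")$pt))))
  val <- tibble(pt = pts)
  cnt <- tibble(pt = pts)
  for (lv in names(results)) {
    s <- results[[lv]]
    if (inherits(s, "pv_screen_skipped")) {
      val[[lv]] <- NA_real_
      cnt[[lv]] <- NA_integer_
    } else {
      i <- match(pts, s$pt)
      val[[lv]] <- s[[metric]][i]
      cnt[[lv]] <- s$a[i]
    }
  }
  structure(val, counts = cnt, metric = metric,
            class = c("pv_heatmap", class(val)))
}

#' Write / read a heatmap matrix as delimited text
#'
#' @param hm a `pv_heatmap`.
#' @param path output path (a sibling `<path>.counts` file carries the
#'   report-count matrix).
#' @param delim delimiter.
#' @return `path` invisibly; `read_heatmap_matrix()` returns the tibble
#'   pair as a list.
#' @export
write_heatmap_matrix <- function(hm, path, delim = "\t") {
  readr::write_delim(as_tibble(hm), path, delim = delim, progress = FALSE)
  readr::write_delim(attr(hm, "counts"), paste0(path, ".counts"),
                     delim = delim, progress = FALSE)
  invisible(path)
}

#' @rdname write_heatmap_matrix
#' @export
read_heatmap_matrix <- function(path, delim = "\t") {
  list(
    values = readr::read_delim(path, delim = delim, show_col_types = FALSE,
                               progress = FALSE),
    counts = readr::read_delim(paste0(path, ".counts"), delim = delim,
                               show_col_types = FALSE, progress = FALSE)
  )
}
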