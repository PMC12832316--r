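#' Summarize a categorical variable by group
#'
#' Counts and percentages per level, with the group size as denominator and
#' the print convention of half-up rounding to two decimals.
#'
#' @param data tibble with one row per report (or per event, if events are
#'   the denominator of interest).
#' @param var column to summarize (unquoted).
#' @param group optional grouping column (unquoted); omitted means one
#'   overall group called `"all"`.
#' @param levels optional character vector declaring the level set (levels
#'   with zero count are then included).
#' @return tibble with columns `group`, `level`, `n`, `pct`.
#' @export
#' @examples
#' d <- tibble::tibble(drug = rep(c("a", "b"), c(4, 6)),
#'                     sex = c("F","F","M","F", "F","M","M","F","F","F"))
#' summarize_categorical(d, sex, drug)
summarize_categorical <- function(data, var, group = NULL, levels = NULL) {
  if (nrow(data) == 0) pv_validation_error("`data` has no rows")
  v <- as.character(eval_select_col(enquo(var), data))
  g <- enquo(group)
  gv <- if (rlang::quo_is_null(g)) rep("all", nrow(data)) else
    as.character(eval_select_col(g, data))
  lv <- levels %||% sort(unique(v))
  out <- tibble(group = gv, level = v) |>
    count(.data$group, .data$level) |>
    tidyr::complete(group = unique(gv), level = lv, fill = list(n = 0L)) |>
    filter(.data$level %in% lv)
  totals <- tibble(group = gv) |> count(.data$group, name = "total")
  out <- left_join(out, totals, by = "group") |>
    mutate(pct = pct_of(.data$n, .data$total)) |>
    select("group", "level", "n", "pct") |>
    arrange(.data$group, match(.data$level, lv))
  out
}

# pull a column by tidy-eval selector
eval_select_col <- function(quo, data) {
  nm <- rlang::as_name(quo)
  if (!nm %in% names(data)) {
    pv_validation_error(paste0("column not found: ", nm))
  }
  data[[nm]]
}

#' Summarize a continuous variable
#'
#' The descriptive block printed for skewed report data: n, missing, mean,
#' sample SD, median, quartiles (linear interpolation between order
#' statistics), min and max.
#'
#' @param x numeric vector with missing values allowed.
#' @return one-row tibble `n`, `missing`, `mean`, `sd`, `median`, `q1`,
#'   `q3`, `min`, `max`; statistics are `NA` when no values are present.
#' @export
#' @examples
#' summarize_continuous(c(1, 2, 3, 4, 5, NA))
summarize_continuous <- function(x) {
  miss <- sum(is.na(x))
  v <- x[!is.na(x)]
  if (length(v) == 0) {
    return(tibble(n = 0L, missing = miss, mean = NA_real_, sd = NA_real_,
                  median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                  min = NA_real_, max = NA_real_))
  }
  q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
  tibble(
    n = length(v), missing = miss,
    mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_,
    median = q[2], q1 = q[1], q3 = q[3],
    min = min(v), max = max(v)
  )
}

#' Distribution of events across system organ classes
#'
#' @param events event-level tibble from [expand_events()].
#' @return tibble `soc`, `n`, `pct` sorted by descending count (ties broken
#'   alphabetically); percentages are of total events, half-up rounded.
#' @export
soc_distribution <- function(events) {
  if (nrow(events) == 0) {
    return(tibble(soc = character(), n = integer(), pct = double()))
  }
  events |>
    count(.data$soc) |>
    mutate(pct = pct_of(.data$n, sum(.data$n))) |>
    arrange(desc(.data$n), .data$soc)
}

#' Compare groups on a categorical variable
#'
#' Pearson chi-square on the r x c count table, switching to Fisher's exact
#' test when any expected cell count is below five (2 x 2 only; larger
#' sparse tables must be collapsed by the caller).  Two-sided throughout,
#' significance at 0.05.
#'
#' @param tab matrix (or table) of non-negative integer counts, at least
#'   2 x 2.
#' @param correct apply the Yates continuity correction to the chi-square
#'   (default `FALSE`).
#' @return one-row tibble `method`, `statistic`, `p_value`, `significant`.
#'   `statistic` is the chi-square statistic, or the conditional odds-ratio
#'   estimate for Fisher's test.
#' @export
#' @examples
#' compare_categorical(matrix(c(85, 72, 465, 576), nrow = 2))
compare_categorical <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    pv_validation_error("counts must be non-negative integers")
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    pv_validation_error("the count table must be at least 2 x 2")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    pv_data_error("degenerate table: a row or column margin is zero")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    if (!all(dim(tab) == c(2, 2))) {
      pv_data_error(paste0(
        "expected cell count < 5 in a table larger than 2 x 2; ",
        "collapse sparse levels before testing"
      ))
    }
    ft <- fisher.test(tab)
    res <- tibble(method = "fisher",
                  statistic = unname(ft$estimate),
                  p_value = ft$p.value)
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    res <- tibble(method = if (correct) "chi2_yates" else "chi2",
                  statistic = unname(ct$statistic),
                  p_value = ct$p.value)
  }
  res$significant <- res$p_value < 0.05
  res
}

#' Compare two samples of a continuous variable
#'
#' Two-sided Mann-Whitney U test, the standard choice for skewed report
#' data such as age or onset time.  Exact enumeration of the rank-sum
#' distribution when both samples are small (min n <= 8) and untied;
#' otherwise the tie-corrected normal approximation (without continuity
#' correction, so identical samples give p = 1).
#'
#' @param x,y numeric samples; missing values are dropped and each sample
#'   must retain at least one value.
#' @return one-row tibble `method`, `statistic` (the U statistic),
#'   `p_value`, `significant`.
#' @export
#' @examples
#' compare_continuous(c(1, 2, 3), c(4, 5, 6))
compare_continuous <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) {
    pv_validation_error("each sample must contain at least one non-missing value")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = FALSE, alternative = "two.sided")
  )
  p <- min(1, wt$p.value)
  tibble(method = "mann_whitney", statistic = unname(wt$statistic),
         p_value = p, significant = p < 0.05)
}
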