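#' Round half away from zero
#'
#' Rounding used for printed percentages in summary tables.  `round()` in R
#' rounds half to even ("banker's rounding"); published safety tables round
#' half up, so 16.255 prints as 16.26.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(16.255, 2.5), 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# percentage of n over total, half-up rounded to 2 decimals (print convention)
pct_of <- function(n, total, digits = 2) {
  round_half_up(100 * n / total, digits)
}

# condition helpers: classed errors so the CLI can map them to exit codes
pv_validation_error <- function(msg, ...) {
  abort(msg, class = c("pv_validation_error", "pv_error"), ...)
}
pv_data_error <- function(msg, ...) {
  abort(msg, class = c("pv_data_error", "pv_error"), ...)
}
pv_convergence_error <- function(msg, ...) {
  abort(msg, class = c("pv_convergence_error", "pv_error"), ...)
}

# flatten a list-column of character vectors to a long (id, value) tibble;
# cheap compared to tidyr::unnest for many small elements
flatten_listcol <- function(ids, values, value_name = "value") {
  lens <- lengths(values)
  out <- tibble(
    primaryid = rep(ids, lens),
    value = unlist(values, use.names = FALSE) %||% character(0)
  )
  names(out)[2] <- value_name
  out
}

# parse FAERS-style yyyymmdd date strings ("" -> NA); partial dates (yyyymm,
# yyyy) are treated as missing rather than guessed
parse_faers_date <- function(x) {
  x <- trimws(x)
  x[!grepl("^[0-9]{8}$", x)] <- NA_character_
  as.Date(x, format = "%Y%m%d")
}

format_faers_date <- function(d) {
  ifelse(is.na(d), "", format(d, "%Y%m%d"))
}
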