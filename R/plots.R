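#' Plot the top terms of a screen
#'
#' Bar chart of the chosen metric for the top-k screened terms, coloured
#' by the number of algorithms flagging each term.
#'
#' @param object a `pv_screen`.
#' @param k number of terms to show.
#' @param metric column to plot (default `"ic"`; the information component
#'   is symmetric around 0 and comparable across term frequencies).
#' @param key ranking passed to [rank_top()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot pv_screen
#' @export
autoplot.pv_screen <- function(object, k = 30, metric = "ic",
                               key = "frequency", ...) {
  rows <- rank_top(object, k, key)
  if (nrow(rows) == 0) pv_data_error("nothing to plot: the screen is empty")
  rows$n_flags <- rows$flag_ror + rows$flag_prr + rows$flag_bcpnn +
    rows$flag_mgps
  rows$pt <- factor(rows$pt, levels = rev(rows$pt))
  ggplot2::ggplot(rows,
                  ggplot2::aes(x = .data[[metric]], y = .data$pt,
                               fill = factor(.data$n_flags))) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_viridis_d(name = "algorithms\nflagging",
                                  drop = FALSE) +
    ggplot2::labs(x = metric, y = NULL,
                  title = paste0("Top ", nrow(rows), " preferred terms (",
                                 key, ")")) +
    ggplot2::theme_minimal()
}

#' Plot a subgroup heatmap matrix
#'
#' Tile map of the chosen metric across preferred terms (rows) and strata
#' (columns); report counts are overprinted, missing cells are blank.
#'
#' @param object a `pv_heatmap`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot pv_heatmap
#' @export
autoplot.pv_heatmap <- function(object, ...) {
  long <- tidy(object)
  long$pt <- factor(long$pt, levels = rev(sort(unique(long$pt))))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$pt,
                                     fill = .data$value)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(is.na(.data$a), "",
                                                   .data$a)), size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  na.value = "grey95",
                                  name = attr(object, "metric")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
plot.pv_screen <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.pv_heatmap <- function(x, ...) print(autoplot(x, ...))
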