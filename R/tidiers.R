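#' Tidy a disproportionality screen
#'
#' @param x a `pv_screen`.
#' @param ... unused.
#' @return the screened rows as a plain tibble (one row per preferred
#'   term, estimator columns and flags).
#' @method tidy pv_screen
#' @export
tidy.pv_screen <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "pv_screen")
  out
}

#' One-row summary of a screen
#'
#' @param x a `pv_screen`.
#' @param ... unused.
#' @return tibble with cohort/background sizes, screened-term count and
#'   per-algorithm flag counts.
#' @method glance pv_screen
#' @export
glance.pv_screen <- function(x, ...) {
  tibble(
    cohort_size = attr(x, "cohort_size"),
    background_size = attr(x, "background_size"),
    n_terms = nrow(x),
    n_flag_ror = sum(x$flag_ror), n_flag_prr = sum(x$flag_prr),
    n_flag_bcpnn = sum(x$flag_bcpnn), n_flag_mgps = sum(x$flag_mgps),
    n_flag_any = sum(x$flag_any), n_flag_all = sum(x$flag_all),
    comparator_mode = attr(x, "comparator_mode")
  )
}

#' Tidy the gamma-Poisson shrinker prior
#'
#' @param x a `gps_prior`.
#' @param ... unused.
#' @return tibble with one row per hyperparameter.
#' @method tidy gps_prior
#' @export
tidy.gps_prior <- function(x, ...) {
  tibble(
    term = c("alpha1", "beta1", "alpha2", "beta2", "p_mix"),
    estimate = c(x$alpha1, x$beta1, x$alpha2, x$beta2, x$p_mix)
  )
}

#' @rdname tidy.gps_prior
#' @method glance gps_prior
#' @export
glance.gps_prior <- function(x, ...) {
  tibble(loglik = x$loglik, n_cells = x$n_cells,
         prior_mean = gps_prior_mean(x), convergence = x$convergence)
}

#' Tidy a heatmap matrix into long format
#'
#' @param x a `pv_heatmap`.
#' @param ... unused.
#' @return long tibble `pt`, `level`, `value`, `a`.
#' @method tidy pv_heatmap
#' @export
tidy.pv_heatmap <- function(x, ...) {
  val <- tidyr::pivot_longer(as_tibble(x), -"pt", names_to = "level",
                             values_to = "value")
  cnt <- tidyr::pivot_longer(attr(x, "counts"), -"pt", names_to = "level",
                             values_to = "a")
  left_join(val, cnt, by = c("pt", "level"))
}
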