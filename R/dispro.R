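#' Build 2x2 contingency rows for drug-event pairs
#'
#' The standard pharmacovigilance 2x2 per drug-event pair: `a` reports with
#' the target drug and the target event, `b` target drug with other events,
#' `c` other drugs with the event, `d` the remainder.  The expected count
#' under independence, `E = (a+b)(a+c)/N`, is always recomputed from the
#' cells.
#'
#' @param a,b,c,d non-negative integer vectors (recycled to a common
#'   length).
#' @return tibble `a`, `b`, `c`, `d`, `n`, `expected`.
#' @export
contingency_table <- function(a, b, c, d) {
  t <- vctrs::vec_recycle_common(a = a, b = b, c = c, d = d)
  cells <- cbind(t$a, t$b, t$c, t$d)
  if (any(cells < 0) || any(cells != round(cells))) {
    pv_validation_error("cells a, b, c, d must be non-negative integers")
  }
  n <- t$a + t$b + t$c + t$d
  if (any(n == 0)) pv_validation_error("N = a+b+c+d must be positive")
  tibble(a = t$a, b = t$b, c = t$c, d = t$d, n = n,
         expected = (t$a + t$b) * (t$a + t$c) / n)
}

#' Reporting odds ratio with 95% Wald interval
#'
#' ROR = ad/bc.  If any cell of a table is zero, 0.5 is added to every cell
#' of that table (Haldane-Anscombe continuity correction) so the estimate
#' and interval stay finite.  The interval is
#' exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)) on the (possibly
#' corrected) cells.
#'
#' @param tab contingency tibble from [contingency_table()].
#' @return tibble `ror`, `ror_lo95`, `ror_hi95` (one row per table).
#' @export
#' @examples
#' disprop_ror(contingency_table(10, 90, 100, 9800))
disprop_ror <- function(tab) {
  zero <- tab$a == 0 | tab$b == 0 | tab$c == 0 | tab$d == 0
  cc <- ifelse(zero, 0.5, 0)
  a <- as.numeric(tab$a) + cc; b <- as.numeric(tab$b) + cc
  c <- as.numeric(tab$c) + cc; d <- as.numeric(tab$d) + cc
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  tibble(ror = ror,
         ror_lo95 = exp(log(ror) - 1.96 * se),
         ror_hi95 = exp(log(ror) + 1.96 * se))
}

#' Proportional reporting ratio with chi-square
#'
#' PRR = [a/(a+b)] / [c/(c+d)] on the raw cells (a = 0 gives PRR 0; no
#' continuity correction is applied here).  The companion statistic is the
#' 2x2 Pearson chi-square, Yates-corrected by convention
#' (`N (|ad-bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))`, clamped at zero).
#'
#' @param tab contingency tibble.
#' @param yates apply the Yates continuity correction (default `TRUE`).
#' @return tibble `prr`, `prr_chi2`.
#' @export
#' @examples
#' disprop_prr(contingency_table(10, 90, 100, 9800))
disprop_prr <- function(tab, yates = TRUE) {
  # doubles throughout: the denominator overflows 32-bit integers easily
  a <- as.numeric(tab$a); b <- as.numeric(tab$b)
  c <- as.numeric(tab$c); d <- as.numeric(tab$d); n <- as.numeric(tab$n)
  prr <- (a / (a + b)) / (c / (c + d))
  adj <- if (yates) n / 2 else 0
  num <- pmax(abs(a * d - b * c) - adj, 0)
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(denom > 0, n * num^2 / denom, NA_real_)
  tibble(prr = prr, prr_chi2 = chi2)
}

#' BCPNN information component with credibility bounds
#'
#' The information component IC = log2((a + 0.5) / (E + 0.5)) with the
#' standard closed-form approximation to the 95% credibility bounds:
#' `ic025 = ic - 3.3 (a+0.5)^-1/2 - 2.0 (a+0.5)^-3/2` and
#' `ic975 = ic + 2.4 (a+0.5)^-1/2 - 0.5 (a+0.5)^-3/2`.
#'
#' @param tab contingency tibble.
#' @return tibble `ic`, `ic025`, `ic975`.
#' @export
#' @examples
#' disprop_ic(contingency_table(10, 90, 100, 9800))
disprop_ic <- function(tab) {
  a5 <- tab$a + 0.5
  ic <- log2(a5 / (tab$expected + 0.5))
  tibble(ic = ic,
         ic025 = ic - 3.3 * a5^(-0.5) - 2.0 * a5^(-1.5),
         ic975 = ic + 2.4 * a5^(-0.5) - 0.5 * a5^(-1.5))
}

# mixture negative-binomial marginal log-likelihood of the gamma-Poisson
# shrinker, evaluated stably in log space
gps_loglik <- function(par, a, e) {
  l1 <- dnbinom(a, size = par[1], prob = par[2] / (par[2] + e), log = TRUE)
  l2 <- dnbinom(a, size = par[3], prob = par[4] / (par[4] + e), log = TRUE)
  lp <- log(par[5]); lq <- log1p(-par[5])
  m <- pmax(l1 + lp, l2 + lq)
  sum(m + log(exp(l1 + lp - m) + exp(l2 + lq - m)))
}

#' Fit the gamma-Poisson shrinker prior
#'
#' Empirical-Bayes hyperparameter estimation for the two-component gamma
#' mixture prior on the report-rate ratio lambda: observed counts `a` are
#' marginally mixtures of two negative binomials given the expected counts
#' `E`.  The five hyperparameters (two shapes, two rates, one mixing
#' weight) are found by bounded quasi-Newton (L-BFGS-B) maximization of the
#' marginal log-likelihood from a fixed start, so the fit is deterministic
#' given the data.
#'
#' @param a observed counts across all screened drug-event cells.
#' @param e expected counts under independence, same length.
#' @param start starting values `(alpha1, beta1, alpha2, beta2, p_mix)`.
#' @param lower,upper box bounds; shapes/rates in `[1e-5, 20]`, mixing
#'   weight in `[1e-3, 1 - 1e-3]`.
#' @return a `gps_prior`: list with `alpha1`, `beta1`, `alpha2`, `beta2`,
#'   `p_mix`, `loglik`, `n_cells`, `convergence`.
#' @export
#' @examples
#' set.seed(1)
#' e <- runif(200, 0.5, 20)
#' a <- rpois(200, e * rgamma(200, shape = 2, rate = 2))
#' gps_fit_prior(a, e)
gps_fit_prior <- function(a, e,
                          start = c(0.2, 0.1, 2.0, 4.0, 1 / 3),
                          lower = c(1e-5, 1e-5, 1e-5, 1e-5, 1e-3),
                          upper = c(20, 20, 20, 20, 1 - 1e-3)) {
  if (length(a) != length(e)) {
    pv_validation_error("`a` and `e` must have the same length")
  }
  if (length(a) < 50) {
    warn(paste0("fitting the shrinker prior on only ", length(a),
                " cells; estimates may be unstable"))
  }
  fit <- optim(start, function(p) -gps_loglik(p, a, e),
               method = "L-BFGS-B", lower = lower, upper = upper,
               control = list(maxit = 500))
  if (fit$convergence != 0 && fit$convergence != 1) {
    pv_convergence_error(paste0(
      "shrinker prior fit failed to converge (code ", fit$convergence, "): ",
      fit$message
    ), trace = fit)
  }
  par <- fit$par
  ll <- -fit$value
  # the optimizer contract: never worse than the start
  if (ll < gps_loglik(start, a, e)) {
    par <- start
    ll <- gps_loglik(start, a, e)
  }
  structure(
    list(alpha1 = par[1], beta1 = par[2], alpha2 = par[3], beta2 = par[4],
         p_mix = par[5], loglik = ll, n_cells = length(a),
         convergence = fit$convergence),
    class = "gps_prior"
  )
}

#' @export
print.gps_prior <- function(x, ...) {
  cat("<gps_prior> gamma mixture: ",
      sprintf("%.4g * Gamma(%.4g, %.4g) + %.4g * Gamma(%.4g, %.4g)",
              x$p_mix, x$alpha1, x$beta1, 1 - x$p_mix, x$alpha2, x$beta2),
      "\n  marginal log-likelihood ", sprintf("%.3f", x$loglik),
      " on ", x$n_cells, " cells\n", sep = "")
  invisible(x)
}

# mean of the prior mixture (used in shrinkage diagnostics)
gps_prior_mean <- function(prior) {
  prior$p_mix * prior$alpha1 / prior$beta1 +
    (1 - prior$p_mix) * prior$alpha2 / prior$beta2
}

#' Posterior EBGM and EB05 under a gamma-Poisson shrinker prior
#'
#' Given the prior, the posterior on lambda for a cell (a, E) is the
#' gamma mixture `Q Gamma(alpha1 + a, beta1 + E) +
#' (1 - Q) Gamma(alpha2 + a, beta2 + E)` with `Q` the posterior mixing
#' weight from the two negative-binomial marginals.  EBGM is the posterior
#' geometric mean `exp(E[ln lambda])` computed via the digamma function;
#' EB05 is the posterior 5th percentile, found by bracketed root-finding on
#' the mixture CDF.
#'
#' @param tab contingency tibble.
#' @param prior a `gps_prior`.
#' @return tibble `ebgm`, `eb05`, `q_post`.
#' @export
gps_ebgm <- function(tab, prior) {
  a <- tab$a; e <- tab$expected
  a1 <- prior$alpha1; b1 <- prior$beta1
  a2 <- prior$alpha2; b2 <- prior$beta2
  l1 <- dnbinom(a, size = a1, prob = b1 / (b1 + e), log = TRUE) +
    log(prior$p_mix)
  l2 <- dnbinom(a, size = a2, prob = b2 / (b2 + e), log = TRUE) +
    log1p(-prior$p_mix)
  m <- pmax(l1, l2)
  q <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
  ebgm <- exp(q * (digamma(a1 + a) - log(b1 + e)) +
                (1 - q) * (digamma(a2 + a) - log(b2 + e)))
  eb05 <- vapply(seq_along(a), function(i) {
    gps_mix_quantile(0.05, q[i], a1 + a[i], b1 + e[i], a2 + a[i], b2 + e[i])
  }, numeric(1))
  tibble(ebgm = ebgm, eb05 = eb05, q_post = q)
}

# quantile of a two-component gamma mixture by root-finding on its CDF;
# the component quantiles bracket the mixture quantile
gps_mix_quantile <- function(p, q, shape1, rate1, shape2, rate2,
                             tol = 1e-10) {
  q1 <- qgamma(p, shape1, rate = rate1)
  q2 <- qgamma(p, shape2, rate = rate2)
  lo <- min(q1, q2); hi <- max(q1, q2)
  if (hi - lo < tol) return((lo + hi) / 2)
  f <- function(x) {
    q * pgamma(x, shape1, rate = rate1) +
      (1 - q) * pgamma(x, shape2, rate = rate2) - p
  }
  # a degenerate mixing weight can put the root at an endpoint
  if (f(lo) >= 0) return(lo)
  if (f(hi) <= 0) return(hi)
  uniroot(f, c(lo, hi), tol = tol)$root
}

#' Conventional signal thresholds
#'
#' The de-facto threshold set used in spontaneous-report screening:
#' ROR rule a >= 3 and lower 95% bound > 1 (van Puijenbroek); PRR rule
#' a >= 3, PRR >= 2 and chi-square >= 4 (Evans); BCPNN rule IC025 > 0
#' (Bate); MGPS rule EB05 > 2 (Szarfman).
#'
#' @param min_a minimum observed count gate for the ROR and PRR rules.
#' @param ror_lo,prr_min,chi2_min,ic025_min,eb05_min rule cut-offs.
#' @return a `signal_thresholds` list.
#' @export
signal_thresholds <- function(min_a = 3, ror_lo = 1, prr_min = 2,
                              chi2_min = 4, ic025_min = 0, eb05_min = 2) {
  structure(
    list(min_a = min_a, ror_lo = ror_lo, prr_min = prr_min,
         chi2_min = chi2_min, ic025_min = ic025_min, eb05_min = eb05_min),
    class = "signal_thresholds"
  )
}

#' @export
print.signal_thresholds <- function(x, ...) {
  cat("<signal_thresholds>",
      sprintf("ror: a>=%d & lo95>%g | prr: a>=%d & prr>=%g & chi2>=%g |",
              x$min_a, x$ror_lo, x$min_a, x$prr_min, x$chi2_min),
      sprintf("bcpnn: ic025>%g | mgps: eb05>%g", x$ic025_min, x$eb05_min),
      "\n")
  invisible(x)
}

#' Per-algorithm signal flags
#'
#' @param metrics tibble containing at least `a`, `ror_lo95`, `prr`,
#'   `prr_chi2`, `ic025`, `eb05`.
#' @param thresholds a [signal_thresholds()] object.
#' @return tibble of logicals `flag_ror`, `flag_prr`, `flag_bcpnn`,
#'   `flag_mgps`, plus aggregates `flag_any` and `flag_all`.
#' @export
signal_flags <- function(metrics, thresholds = signal_thresholds()) {
  th <- thresholds
  f_ror <- metrics$a >= th$min_a & metrics$ror_lo95 > th$ror_lo
  f_prr <- metrics$a >= th$min_a & metrics$prr >= th$prr_min &
    metrics$prr_chi2 >= th$chi2_min
  f_bcp <- metrics$ic025 > th$ic025_min
  f_mgps <- metrics$eb05 > th$eb05_min
  tibble(flag_ror = f_ror, flag_prr = f_prr, flag_bcpnn = f_bcp,
         flag_mgps = f_mgps,
         flag_any = f_ror | f_prr | f_bcp | f_mgps,
         flag_all = f_ror & f_prr & f_bcp & f_mgps)
}

#' All four estimators on contingency rows
#'
#' Convenience wrapper evaluating ROR, PRR, IC and (given a prior) the
#' shrinker posterior on every row, with signal flags.
#'
#' @param tab contingency tibble.
#' @param prior optional `gps_prior`; when `NULL` it is fitted on
#'   the supplied cells.
#' @param thresholds a [signal_thresholds()] object.
#' @param yates Yates correction for the PRR chi-square.
#' @return `tab` with the estimator and flag columns appended.
#' @export
signal_metrics <- function(tab, prior = NULL,
                           thresholds = signal_thresholds(), yates = TRUE) {
  if (is.null(prior)) prior <- gps_fit_prior(tab$a, tab$expected)
  out <- bind_cols(tab, disprop_ror(tab), disprop_prr(tab, yates = yates),
                   disprop_ic(tab), gps_ebgm(tab, prior))
  bind_cols(out, signal_flags(out, thresholds))
}

#' Null calibration of the estimators by independence simulation
#'
#' Simulates 2x2 tables under independence with fixed report margins: the
#' target cohort and comparator each draw event counts from the same
#' binomial event probability.  Reports the fraction of replicates whose
#' ROR 95% interval covers 1 and the fraction with IC025 > 0 (the BCPNN
#' false-positive rate).
#'
#' @param n_rep number of replicates.
#' @param n_target,n_comparator report counts in the two margins.
#' @param p_event per-report event probability.
#' @param seed RNG seed.
#' @return one-row tibble `ror_coverage`, `ic_positive_rate`, `n_rep`.
#' @export
null_calibration <- function(n_rep = 1000, n_target = 500,
                             n_comparator = 10000, p_event = 0.02,
                             seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  a <- rbinom(n_rep, n_target, p_event)
  c <- rbinom(n_rep, n_comparator, p_event)
  tab <- contingency_table(a, n_target - a, c, n_comparator - c)
  ror <- disprop_ror(tab)
  ic <- disprop_ic(tab)
  tibble(
    ror_coverage = mean(ror$ror_lo95 <= 1 & ror$ror_hi95 >= 1),
    ic_positive_rate = mean(ic$ic025 > 0),
    n_rep = n_rep
  )
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
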