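test_that("contingency rows recompute N and the expected count", {
  t <- contingency_table(10, 90, 100, 9800)
  expect_equal(t$n, 10000)
  expect_equal(t$expected, 100 * 110 / 10000)
  expect_error(contingency_table(-1, 0, 0, 1), class = "pv_validation_error")
  expect_error(contingency_table(0, 0, 0, 0), class = "pv_validation_error")
})

test_that("ROR matches its closed form and handles zero cells", {
  r <- disprop_ror(contingency_table(10, 90, 100, 9800))
  expect_equal(r$ror, 10 * 9800 / (90 * 100), tolerance = 1e-12)
  expect_equal(r$ror_lo95, 5.50, tolerance = 0.01)
  expect_equal(r$ror_hi95, 21.55, tolerance = 0.01)

  sym <- disprop_ror(contingency_table(10, 10, 10, 10))
  expect_equal(sym$ror, 1)
  expect_true(sym$ror_lo95 < 1 && sym$ror_hi95 > 1)

  z <- disprop_ror(contingency_table(0, 10, 10, 100))
  expect_true(is.finite(z$ror) && z$ror > 0)
  expect_equal(z$ror, (0.5 * 100.5) / (10.5 * 10.5), tolerance = 1e-12)
})

test_that("PRR and its Yates chi-square match direct evaluation", {
  p <- disprop_prr(contingency_table(10, 90, 100, 9800))
  expect_equal(p$prr, (10 / 100) / (100 / 9900), tolerance = 1e-12)
  expect_equal(p$prr_chi2, 65.5, tolerance = 0.01)
  # against stats::chisq.test with continuity correction
  ref <- suppressWarnings(chisq.test(matrix(c(10, 100, 90, 9800), 2),
                                     correct = TRUE))
  expect_equal(p$prr_chi2, unname(ref$statistic), tolerance = 1e-9)

  flat <- disprop_prr(contingency_table(10, 90, 100, 900))
  expect_equal(flat$prr, 1)
  expect_lt(flat$prr_chi2, 0.1)
  expect_equal(disprop_prr(contingency_table(0, 10, 5, 85))$prr, 0)
})

test_that("information component and credibility bounds match closed forms", {
  k <- contingency_table(7, 7, 7, 7)   # a equals its expectation
  expect_equal(disprop_ic(k)$ic, 0)

  t <- contingency_table(10, 90, 100, 9800)
  ic <- disprop_ic(t)
  expect_equal(ic$ic, log2(10.5 / 1.6), tolerance = 1e-12)
  expect_equal(ic$ic025, log2(10.5 / 1.6) - 3.3 / sqrt(10.5) - 2 / 10.5^1.5,
               tolerance = 1e-12)
  expect_equal(ic$ic025, 1.637, tolerance = 0.01)

  # interval width vanishes as a grows with a/E fixed
  big <- disprop_ic(contingency_table(10000, 90000, 100000, 9800000))
  expect_lt(big$ic - big$ic025, 0.05)
})

test_that("estimator closed forms match brute-force recomputation", {
  tabs <- random_tables(1000, seed = 101)
  ror <- disprop_ror(tabs); prr <- disprop_prr(tabs); ic <- disprop_ic(tabs)
  for (i in seq_len(nrow(tabs))) {
    a <- tabs$a[i]; b <- tabs$b[i]; c <- tabs$c[i]; d <- tabs$d[i]
    n <- a + b + c + d
    # odds formulation, written independently of the implementation
    odds1 <- (a / (a + b)) / (1 - a / (a + b))
    odds0 <- (c / (c + d)) / (1 - c / (c + d))
    expect_equal(ror$ror[i], odds1 / odds0, tolerance = 1e-9)
    expect_equal(prr$prr[i], (a / (a + b)) / (c / (c + d)), tolerance = 1e-9)
    e <- (a + b) / n * (a + c)
    expect_equal(ic$ic[i], (log(a + 0.5) - log(e + 0.5)) / log(2),
                 tolerance = 1e-9)
  }
})

test_that("sign coherence and the ROR >= PRR identity hold", {
  tabs <- random_tables(500, seed = 7)
  m <- cbind(disprop_ror(tabs)$ror - 1, disprop_prr(tabs)$prr - 1,
             disprop_ic(tabs)$ic)
  nonzero <- abs(m[, 1]) > 1e-9
  expect_true(all(m[nonzero, 1] * m[nonzero, 2] >= 0))
  expect_true(all(m[nonzero, 1] * m[nonzero, 3] >= 0))
  up <- disprop_ror(tabs)$ror > 1
  expect_true(all(disprop_ror(tabs)$ror[up] >= disprop_prr(tabs)$prr[up]))
})

test_that("the shrinker prior recovers a known single-gamma prior", {
  set.seed(23)
  n <- 10000
  e <- runif(n, 0.5, 20)
  lambda <- rgamma(n, shape = 2, rate = 4)     # prior mean 0.5
  a <- rpois(n, lambda * e)
  prior <- gps_fit_prior(a, e)
  expect_equal(prior$convergence, 0)
  mix_mean <- prior$p_mix * prior$alpha1 / prior$beta1 +
    (1 - prior$p_mix) * prior$alpha2 / prior$beta2
  expect_equal(mix_mean, 0.5, tolerance = 0.05)   # within 10% of 0.5
  # the optimum cannot be worse than the fixed start
  start_ll <- sum(log(
    1 / 3 * dnbinom(a, size = 0.2, prob = 0.1 / (0.1 + e)) +
      2 / 3 * dnbinom(a, size = 2, prob = 4 / (4 + e))
  ))
  expect_gte(prior$loglik, start_ll)
})

test_that("the prior fit survives degenerate all-zero data", {
  e <- rep(2, 100)
  expect_no_error(prior <- gps_fit_prior(rep(0L, 100), e))
  expect_lt(gps_prior_mean(prior), 0.2)
  expect_warning(gps_fit_prior(rep(0L, 10), rep(1, 10)), "cells")
})

test_that("EBGM and EB05 match the collapsed-prior closed forms", {
  # both mixture components Gamma(1,1): posterior for (a=0, E=1) is
  # Gamma(1,2) whatever the weight
  prior <- structure(list(alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1,
                          p_mix = 0.999), class = "gps_prior")
  t <- contingency_table(0, 10, 10, 100)
  t$expected <- 1   # pin E exactly
  post <- gps_ebgm(t, prior)
  expect_equal(post$ebgm, exp(digamma(1) - log(2)), tolerance = 1e-9)
  expect_equal(post$eb05, -log(0.95) / 2, tolerance = 1e-8)
})

test_that("shrinkage pulls EBGM between the prior and the raw ratio", {
  # EBGM is a posterior geometric mean, so the natural lower envelope is
  # the prior geometric mean (the arithmetic prior mean can exceed it)
  set.seed(31)
  for (i in 1:50) {
    prior <- structure(list(alpha1 = runif(1, 0.5, 3), beta1 = runif(1, 0.5, 3),
                            alpha2 = runif(1, 0.5, 3), beta2 = runif(1, 0.5, 3),
                            p_mix = runif(1, 0.1, 0.9)), class = "gps_prior")
    a <- sample(3:80, 1)
    t <- contingency_table(a, sample(10:200, 1), sample(10:200, 1),
                           sample(2000:20000, 1))
    obs <- a / t$expected
    pm <- gps_prior_mean(prior)
    gm <- exp(prior$p_mix * (digamma(prior$alpha1) - log(prior$beta1)) +
                (1 - prior$p_mix) * (digamma(prior$alpha2) -
                                       log(prior$beta2)))
    eb <- gps_ebgm(t, prior)$ebgm
    expect_gt(eb, min(obs, gm) * 0.95)
    expect_lt(eb, max(obs, pm) * 1.001)
  }
  prior <- structure(list(alpha1 = 0.5, beta1 = 0.8, alpha2 = 2, beta2 = 2,
                          p_mix = 0.3), class = "gps_prior")
  # monotone non-decreasing in a at fixed E
  tt <- contingency_table(0:30, 50, 100, 10000)
  tt$expected <- rep(5, 31)
  expect_true(all(diff(gps_ebgm(tt, prior)$ebgm) > -1e-10))
  # shrinkage vanishes in the data limit: ebgm -> a/E
  for (r in c(0.5, 2, 5)) {
    big <- contingency_table(round(r * 1e5), 1e5, 1e5, 1e7)
    big$expected <- 1e5
    expect_equal(gps_ebgm(big, prior)$ebgm, r, tolerance = 1e-4)
  }
})

test_that("EB05 agrees with brute-force numerical CDF inversion", {
  set.seed(47)
  for (i in 1:100) {
    prior <- structure(list(alpha1 = runif(1, 0.2, 4), beta1 = runif(1, 0.2, 4),
                            alpha2 = runif(1, 0.2, 4), beta2 = runif(1, 0.2, 4),
                            p_mix = runif(1, 0.05, 0.95)), class = "gps_prior")
    t <- contingency_table(sample(0:50, 1), sample(5:200, 1),
                           sample(5:200, 1), sample(1000:20000, 1))
    post <- gps_ebgm(t, prior)
    # oracle: integrate the posterior mixture density, bisect on the CDF
    s1 <- prior$alpha1 + t$a; r1 <- prior$beta1 + t$expected
    s2 <- prior$alpha2 + t$a; r2 <- prior$beta2 + t$expected
    q <- post$q_post
    dens <- function(x) q * dgamma(x, s1, rate = r1) +
      (1 - q) * dgamma(x, s2, rate = r2)
    cdf <- function(x) integrate(dens, 0, x, rel.tol = 1e-10)$value
    lo <- 0; hi <- max(qgamma(0.999, s1, rate = r1),
                       qgamma(0.999, s2, rate = r2))
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (cdf(mid) < 0.05) lo <- mid else hi <- mid
    }
    expect_equal(post$eb05, (lo + hi) / 2, tolerance = 1e-6)
  }
})

test_that("signal flags follow the threshold rules exactly", {
  th <- signal_thresholds()
  m <- tibble::tibble(
    a = c(2L, 10L, 10L, 10L),
    ror_lo95 = c(50, 5.5, 0.9, 2),
    prr = c(9, 9.9, 1, 3), prr_chi2 = c(60, 65.5, 0.1, 10),
    ic025 = c(1, 1.6, 0, -0.2), eb05 = c(3, 4, 2, 1)
  )
  f <- signal_flags(m, th)
  expect_false(f$flag_ror[1])     # a >= 3 gate despite huge ror
  expect_true(f$flag_ror[2] && f$flag_prr[2])
  expect_false(f$flag_bcpnn[3])   # strict > at the boundary
  expect_false(f$flag_mgps[3])    # strict > at the boundary
  expect_true(f$flag_any[1])
  expect_equal(f$flag_all, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("null simulation calibrates the interval estimators", {
  cal <- null_calibration(n_rep = 300, seed = 5)
  expect_gt(cal$ror_coverage, 0.90)
  expect_lt(cal$ic_positive_rate, 0.06)
})
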