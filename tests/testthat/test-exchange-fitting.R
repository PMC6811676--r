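# Inference: global z-z fit, build-up fit, normalized-ratio fit,
# mediated-NOE fit, and per-site aggregation.

test_that("global z-z fit recovers generating rates from noiseless data", {
  sys <- exchange_system(3.5, 7.7, 2.0)
  z <- simulate_nh2_nh_zz(sys, default_delays, retention_factor = 0.5)
  fit <- fit_global_zz(z)
  expect_true(fit$converged)
  expect_equal(fit$k1_hat, 3.5, tolerance = 1e-4)
  expect_equal(fit$k_rev_hat, 7.7, tolerance = 1e-4)
  expect_equal(fit$R1_hat, 2.0, tolerance = 1e-4)
  expect_true(all(is.finite(fit$se[c("k1", "k_rev", "R1")])))
})

test_that("global z-z fit returns near-zero rates for exchange-free data", {
  sys <- exchange_system(0, 0, 2.0)
  z <- simulate_nh2_nh_zz(sys, default_delays)
  fit <- fit_global_zz(z)
  expect_lt(fit$k1_hat, 1e-3)
  expect_lt(fit$k_rev_hat, 1e-3)
})

test_that("global z-z fit validates its inputs", {
  sys <- exchange_system(3.5, 7.7, 2.0)
  z <- simulate_nh2_nh_zz(sys, default_delays)
  expect_error(fit_global_zz(z[c("NH2", "NH")]), "missing curve label")
  z3 <- simulate_nh2_nh_zz(sys, c(0.1, 0.2, 0.3))
  expect_error(fit_global_zz(z3), "4 distinct delays")
})

test_that("noisy z-z recovery has bounded median error", {
  errs <- unlist(recovery_study("default_zz", reps = 25, seed = 100)["k1"])
  expect_lt(errs, 0.15)
})

test_that("build-up fit recovers k_ex and locates the curve maximum", {
  kex <- 11.2; R1 <- 2.0
  v <- (1 - exp(-kex * default_delays)) * exp(-R1 * default_delays)
  fit <- fit_buildup_sum(volume_series("aA", default_delays, v))
  expect_equal(fit$k_ex_hat, kex, tolerance = 1e-4)
  expect_equal(fit$estimates[["R1"]], R1, tolerance = 1e-4)
  # analytic maximum location, checked against a dense grid
  tstar <- log(1 + kex / R1) / kex
  expect_equal(tstar, 0.1685, tolerance = 1e-3)
  tg <- seq(0.001, 0.8, by = 1e-4)
  vg <- (1 - exp(-kex * tg)) * exp(-R1 * tg)
  expect_equal(tg[which.max(vg)], tstar, tolerance = 1e-3)
})

test_that("build-up fit flags degenerate inputs", {
  z <- fit_buildup_sum(volume_series("aA", default_delays,
                                     rep(0, length(default_delays))))
  expect_false(z$converged)
  expect_match(z$flags, "unidentifiable")
  expect_equal(z$estimates[["C"]], 0)
  # monotone build-up only: R1 unconstrained
  v <- 1 - exp(-3 * default_delays)
  f <- fit_buildup_sum(volume_series("aA", default_delays, v))
  expect_match(paste(f$flags, collapse = " "), "unconstrained R1")
})

test_that("normalized-ratio fit separates k1 and k_rev", {
  cur <- noesy_curves(k1 = 4.3, k_rev = 8.8)
  fit <- fit_normalized_rates(cur$aA, cur$AA)
  expect_equal(fit$k1_hat, 4.3, tolerance = 1e-4)
  expect_equal(fit$k_rev_hat, 8.8, tolerance = 1e-4)
  # plateau of the noiseless ratio is the minor population
  sys <- exchange_system(4.3, 8.8, 2.0)
  long <- simulate_two_site(sys, 5)
  expect_equal(long$aA$volume / (long$AA$volume + long$aA$volume),
               populations(sys)[["p_minor"]], tolerance = 1e-6)
  expect_error(
    fit_normalized_rates(volume_series("aA", c(0.1, 0.2), c(0.1, 0.1)),
                         volume_series("AA", c(0.1, 0.3), c(1, 1))),
    "delay grid")
})

test_that("normalized-ratio fit has small bias under noise", {
  set.seed(11)
  true_kex <- 4.3 + 8.8
  kex_hat <- vapply(1:60, function(r) {
    cfg <- scenario_config(k1 = 4.3, k_rev = 8.8, R1 = 2.0, noise_sd = 0.05,
                           seed = 5000 + r)
    site <- generate_noesy_dataset(cfg)$sites$site1
    fit_normalized_rates(site$aA, site$AA)$k_ex_hat
  }, numeric(1))
  expect_lt(abs(mean(kex_hat) - true_kex) / true_kex, 0.05)
})

test_that("build-up and normalized fits agree on k_ex", {
  # sigma-free curves: the build-up closed form is then exact
  cur <- noesy_curves(k1 = 4.3, k_rev = 8.8, sigma = 0)
  kex_buildup <- fit_buildup_sum(cur$aA)$k_ex_hat
  kex_norm <- fit_normalized_rates(cur$aA, cur$AA)$k_ex_hat
  expect_equal(kex_buildup, kex_norm, tolerance = 1e-3)
  expect_equal(kex_norm, 13.1, tolerance = 1e-3)
})

test_that("mediated-NOE ratio fit recovers the individual rates", {
  cur <- noesy_curves(k1 = 4.3, k_rev = 8.8, sigma = -1.0)
  fit <- fit_mediated_noe(cur$Ab, cur$AB)
  expect_true(fit$converged)
  expect_equal(fit$k1_hat, 4.3, tolerance = 0.05)
  expect_equal(fit$k_rev_hat, 8.8, tolerance = 0.05)
  # the aB/(ab+aB) orientation works symmetrically
  fit2 <- fit_mediated_noe(cur$aB, cur$ab)
  expect_equal(fit2$k1_hat, 4.3, tolerance = 0.05)
})

test_that("mediated-NOE fit flags unidentifiable input", {
  cur <- noesy_curves(k1 = 0, k_rev = 0, sigma = -1.0)
  f <- fit_mediated_noe(cur$Ab, cur$AB)
  expect_false(f$converged)
  expect_equal(f$k1_hat, 0)
  cur0 <- noesy_curves(sigma = 0)
  f0 <- fit_mediated_noe(cur0$Ab, cur0$AB)
  expect_false(f0$converged)
  expect_match(paste(f0$flags, collapse = " "), "unidentifiable")
})

test_that("mediated ratio curves are monotone non-decreasing (noiseless)", {
  set.seed(3)
  for (i in 1:10) {
    k1 <- runif(1, 1, 10); kr <- runif(1, 1, 10)
    cur <- noesy_curves(k1 = k1, k_rev = kr, sigma = -runif(1, 0.3, 2),
                        delays = seq(0.01, 0.8, length.out = 25))
    q <- cur$Ab$volume / (cur$AB$volume + cur$Ab$volume)
    expect_true(all(diff(q) > -1e-9))
  }
})

test_that("noise ladder: more noise never reduces median k_ex error", {
  levels <- c(0.01, 0.05, 0.2)
  med <- vapply(levels, function(sd) {
    errs <- vapply(1:50, function(r) {
      cfg <- scenario_config(k1 = 4.3, k_rev = 8.8, R1 = 2, noise_sd = sd,
                             seed = 70000 + r)
      site <- generate_noesy_dataset(cfg)$sites$site1
      abs(fit_normalized_rates(site$aA, site$AA)$k_ex_hat - 13.1) / 13.1
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
})

test_that("aggregate_sites summarizes converged results", {
  mk <- function(k1, kr, conv = TRUE) {
    r <- fit_normalized_rates(
      volume_series("aA", default_delays,
                    k1 / (k1 + kr) * (1 - exp(-(k1 + kr) * default_delays))),
      volume_series("AA", default_delays,
                    1 - k1 / (k1 + kr) * (1 - exp(-(k1 + kr) * default_delays))))
    r$converged <- conv
    r
  }
  five <- replicate(5, mk(4.3, 8.8), simplify = FALSE)
  agg <- aggregate_sites(five)
  expect_equal(unname(agg$mean["k1"]), 4.3, tolerance = 1e-3)
  expect_equal(unname(agg$sd["k1"]), 0, tolerance = 1e-6)
  two <- list(mk(3.8, 8), mk(5.2, 8))
  agg2 <- aggregate_sites(two)
  expect_equal(unname(agg2$mean["k1"]), 4.5, tolerance = 1e-3)
  expect_equal(unname(agg2$sd["k1"]), 0.9899495, tolerance = 1e-3)
  withdrop <- aggregate_sites(c(two, list(mk(99, 1, conv = FALSE))))
  expect_equal(withdrop$n_used, 2)
  expect_equal(withdrop$n_dropped, 1)
  expect_error(aggregate_sites(list()), "no fit results")
})
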