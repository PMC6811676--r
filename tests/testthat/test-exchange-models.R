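# Forward models: closed forms, rate-matrix propagation, and the
# amide/amine and four-pool schemes, checked against independent oracles.

test_that("two-site closed form matches trivial limits", {
  # no exchange: pure R1 decay, no cross peak
  sys <- exchange_system(0, 0, 2)
  s <- simulate_two_site(sys, c(0, 0.1))
  expect_equal(s$AA$volume, c(1, exp(-0.2)))
  expect_equal(s$aA$volume, c(0, 0))
  # t = 0: full auto intensity, zero cross, any system
  sys <- exchange_system(3.5, 7.7, 2)
  s <- simulate_two_site(sys, 0)
  expect_equal(s$AA$volume, 1)
  expect_equal(s$aa$volume, 1)
  expect_equal(s$aA$volume, 0)
  expect_equal(s$Aa$volume, 0)
})

test_that("normalized cross fraction matches expm and ODE oracles", {
  sys <- exchange_system(3.5, 7.7, 2.0)
  s <- simulate_two_site(sys, 0.1)
  frac <- s$aA$volume / (s$AA$volume + s$aA$volume)
  p_minor <- populations(sys)[["p_minor"]]
  expect_equal(frac, p_minor * (1 - exp(-sys$k_ex * 0.1)), tolerance = 1e-12)
  expect_equal(round(frac, 4), 0.2105)

  G <- rate_matrix_two_site(sys)
  M_expm <- propagate_rate_matrix(G, c(1, 0), 0.1)
  expect_equal(unname(M_expm[, 1]), c(s$AA$volume, s$aA$volume),
               tolerance = 1e-10)
  M_ode <- ode_propagate(G, c(1, 0), 0.1)
  expect_equal(unname(M_ode[, 1]), c(s$AA$volume, s$aA$volume),
               tolerance = 1e-8)
})

test_that("propagation satisfies identity and scalar-decay limits", {
  M <- propagate_rate_matrix(matrix(0, 2, 2), c(0.3, 0.7), c(0, 1, 10))
  expect_equal(unname(M), matrix(c(0.3, 0.7), 2, 3), tolerance = 1e-12)
  M1 <- propagate_rate_matrix(matrix(-2, 1, 1), 1, c(0, 0.5, 1))
  expect_equal(unname(M1[1, ]), exp(-2 * c(0, 0.5, 1)), tolerance = 1e-12)
})

test_that("propagation validates its inputs", {
  expect_error(propagate_rate_matrix(matrix(0, 2, 3), c(1, 0), 0.1),
               "square")
  expect_error(propagate_rate_matrix(matrix(0, 2, 2), c(1, 0, 0), 0.1),
               "pools")
  expect_error(propagate_rate_matrix(matrix(c(-1, -0.1, 1, -1), 2, 2),
                                     c(1, 0), 0.1),
               "off-diagonal")
  expect_error(simulate_two_site(exchange_system(1, 1, 1), c(0.1, -0.2)),
               "index 2")
  expect_error(populations(exchange_system(0, 0, 1)), "undefined")
})

test_that("closed form, matrix exponential and ODE agree on random systems", {
  set.seed(42)
  delays <- c(0.01, 0.05, 0.2, 0.8)
  for (i in 1:100) {
    sys <- random_system()
    s <- simulate_two_site(sys, delays)
    G <- rate_matrix_two_site(sys)
    closed <- rbind(s$AA$volume, s$aA$volume)
    M <- propagate_rate_matrix(G, c(1, 0), delays)
    expect_equal(unname(M), unname(closed), tolerance = 1e-10)
  }
  # ODE cross-check on a subsample (slow oracle)
  for (i in 1:10) {
    sys <- random_system()
    G <- rate_matrix_two_site(sys)
    expect_equal(unname(propagate_rate_matrix(G, c(0.4, 0.6), delays)),
                 unname(ode_propagate(G, c(0.4, 0.6), delays)),
                 tolerance = 1e-8)
  }
})

test_that("exchange-only stationary distribution obeys detailed balance", {
  set.seed(7)
  for (i in 1:20) {
    sys <- exchange_system(runif(1, 0.1, 50), runif(1, 0.1, 50), 0)
    G <- rate_matrix_two_site(sys)
    M <- propagate_rate_matrix(G, c(1, 0), 50 / sys$k_ex)
    expect_equal(unname(M[, 1]),
                 unname(populations(sys)[c("p_major", "p_minor")]),
                 tolerance = 1e-6)
  }
})

test_that("normalized cross-peak plateau approaches the minor population", {
  sys <- exchange_system(3.5, 7.7, 2.0)
  s <- simulate_two_site(sys, 3)    # >> 1/k_ex; R1 cancels in the ratio
  frac <- s$aA$volume / (s$AA$volume + s$aA$volume)
  expect_equal(frac, populations(sys)[["p_minor"]], tolerance = 1e-6)
})

test_that("amide/amine scheme reduces and conserves as expected", {
  sys <- exchange_system(3.5, 7.7, 2.0)
  delays <- c(0.02, 0.1, 0.3)
  # retention 1 reduces to the two-site closed form
  z <- simulate_nh2_nh_zz(sys, delays, retention_factor = 1)
  s <- simulate_two_site(sys, delays)
  expect_equal(z$`NH2`$volume, s$AA$volume, tolerance = 1e-10)
  expect_equal(z$`NH'`$volume, s$aA$volume, tolerance = 1e-10)
  expect_equal(z$`NH2'`$volume, s$Aa$volume, tolerance = 1e-10)
  # no exchange: no exchange peaks
  z0 <- simulate_nh2_nh_zz(exchange_system(0, 0, 2), delays)
  expect_true(all(z0$`NH2'`$volume == 0))
  expect_true(all(z0$`NH'`$volume == 0))
  # conservation with R1 = 0 and retention 1
  G <- rate_matrix_two_site(exchange_system(3.5, 7.7, 0), 1)
  M <- propagate_rate_matrix(G, c(0.25, 0.75), c(0.1, 1, 10))
  expect_equal(unname(colSums(M)), rep(1, 3), tolerance = 1e-10)
  expect_error(simulate_nh2_nh_zz(sys, delays, retention_factor = 1.2),
               "retention_factor")
})

test_that("amide/amine exchange peaks build up then decay", {
  sys <- exchange_system(3.5, 7.7, 2.0)
  dense <- seq(0.001, 0.8, by = 0.001)
  z <- simulate_nh2_nh_zz(sys, dense, retention_factor = 0.5)
  for (lab in c("NH2'", "NH'")) {
    v <- z[[lab]]$volume
    imax <- which.max(v)
    expect_gt(imax, 1)
    expect_lt(imax, length(v))
    # agrees with the ODE oracle at a few delays
    G <- rate_matrix_two_site(sys, 0.5)
    sub <- c(0.05, 0.2, 0.5)
    idx <- vapply(sub, function(t0)
      which.min(abs(z[[lab]]$t_mix_s - t0)), integer(1))
    M <- ode_propagate(G, if (lab == "NH'") c(1, 0) else c(0, 1),
                       z[[lab]]$t_mix_s[idx])
    row <- if (lab == "NH'") 2 else 1
    expect_equal(unname(M[row, ]), v[idx], tolerance = 1e-8)
  }
})

test_that("four-pool scheme has the expected zero-path structure", {
  delays <- c(0.02, 0.1, 0.4)
  # no NOE: no mediated or direct NOE peaks
  cur <- noesy_curves(sigma = 0, delays = delays)
  for (lab in c("Ab", "aB", "AB", "ab"))
    expect_true(all(cur[[lab]]$volume == 0), label = lab)
  # no exchange: no exchange cross peaks
  pair <- noe_pair_system(exchange_system(0, 0, 2), -1)
  cur <- simulate_exchange_noe(pair, delays)
  for (lab in c("Aa", "aA"))
    expect_true(all(cur[[lab]]$volume == 0), label = lab)
})

test_that("four-pool propagation matches brute-force ODE integration", {
  pair <- noe_pair_system(exchange_system(4.3, 8.8, 2.0), -1.0)
  delays <- c(0.01, 0.05, 0.2, 0.8)
  G <- rate_matrix_noe_pair(pair)
  p <- populations(pair$exchange)
  for (origin in 1:4) {
    m0 <- numeric(4)
    m0[origin] <- c(p[1], p[2], p[1], p[2])[origin]
    expect_equal(unname(propagate_rate_matrix(G, m0, delays)),
                 unname(ode_propagate(G, m0, delays)),
                 tolerance = 1e-8)
  }
})

test_that("volume series validate and serialize round trip", {
  expect_error(volume_series("XX", 1, 1), "unknown peak label")
  expect_error(volume_series("AA", c(0.2, 0.1), c(1, 1)), "increasing")
  expect_error(volume_series("AA", c(0.1, 0.2), 1), "equal length")
  s1 <- volume_series("AA", c(0.1, 0.2), c(1, 0.8), c(0.05, 0.04))
  s2 <- volume_series("aA", c(0.1, 0.2), c(0, 0.2))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_volume_series(list(s1, s2), tmp)
  back <- read_volume_series(tmp)
  expect_named(back, c("AA", "aA"))
  expect_equal(back$AA$volume, s1$volume)
  expect_equal(back$AA$sigma_volume, s1$sigma_volume)
  expect_equal(back$aA$t_mix_s, s2$t_mix_s)
})
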