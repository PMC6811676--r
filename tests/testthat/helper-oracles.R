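# Independent oracles used across the suite.

# brute-force ODE integration of dM/dt = G M (independent of the package's
# eigendecomposition path)
ode_propagate <- function(G, m0, delays) {
  f <- function(t, y, parms) list(as.numeric(G %*% y))
  times <- sort(unique(c(0, delays)))
  out <- deSolve::lsoda(y = m0, times = times, func = f, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  idx <- match(delays, out[, 1])
  t(out[idx, -1, drop = FALSE])
}

# random two-site systems with rates in [0, 50] s^-1
random_system <- function() {
  exchange_system(k1 = runif(1, 0, 50), k_rev = runif(1, 0, 50),
                  R1 = runif(1, 0, 5))
}

default_delays <- exp(seq(log(0.01), log(0.5), length.out = 16))

# noiseless four-pool curves for the NOESY-style fits
noesy_curves <- function(k1 = 4.3, k_rev = 8.8, R1 = 2.0, sigma = -1.0,
                         delays = default_delays) {
  pair <- noe_pair_system(exchange_system(k1, k_rev, R1), sigma)
  simulate_exchange_noe(pair, delays)
}
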