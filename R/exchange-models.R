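# Forward models of longitudinal magnetization exchange.
#
# All kinetic schemes are expressed as a generator matrix G acting on the
# vector of pool magnetizations, dM/dt = G M, with non-negative
# off-diagonal transfer rates and diagonal entries carrying the losses
# (including R1 auto-relaxation).  Propagation is by matrix exponential.

#' Build the generator matrix of a two-site exchange system
#'
#' @param system An [exchange_system()].
#' @param retention_factor Fraction of pool-1 magnetization carried into
#'   pool 2 on major -> minor conversion (1 = magnetization-conserving
#'   exchange; see [simulate_nh2_nh_zz()] for the amide/amine use).
#' @return 2x2 generator with rows/columns `(label_major, label_minor)`.
#' @export
rate_matrix_two_site <- function(system, retention_factor = 1) {
  stopifnot(inherits(system, "exchange_system"))
  if (!is.numeric(retention_factor) || length(retention_factor) != 1L ||
      retention_factor < 0 || retention_factor > 1)
    stop("'retention_factor' must be in [0, 1]")
  G <- matrix(c(-system$k1 - system$R1, system$k_rev,
                retention_factor * system$k1, -system$k_rev - system$R1),
              nrow = 2, byrow = TRUE)
  dimnames(G) <- list(c(system$label_major, system$label_minor),
                      c(system$label_major, system$label_minor))
  G
}

#' Build the generator matrix of a four-pool exchange + NOE system
#'
#' Pools are ordered `A, a, B, b` (proton X major/minor, proton Y
#' major/minor).  Exchange connects `A<->a` and `B<->b`; cross-relaxation
#' connects `A<->B` (rate `|sigma_major|`) and `a<->b` (`|sigma_minor|`).
#'
#' @param pair A [noe_pair_system()].
#' @return 4x4 generator matrix.
#' @export
rate_matrix_noe_pair <- function(pair) {
  stopifnot(inherits(pair, "noe_pair_system"))
  ex <- pair$exchange
  sA <- abs(pair$sigma_major); sB <- abs(pair$sigma_minor)
  k1 <- ex$k1; kr <- ex$k_rev; R1 <- ex$R1
  pools <- c("A", "a", "B", "b")
  G <- matrix(0, 4, 4, dimnames = list(pools, pools))
  # exchange
  G["a", "A"] <- k1; G["A", "a"] <- kr
  G["b", "B"] <- k1; G["B", "b"] <- kr
  # cross-relaxation within conformers
  G["B", "A"] <- sA; G["A", "B"] <- sA
  G["b", "a"] <- sB; G["a", "b"] <- sB
  diag(G) <- -colSums(G) - R1
  G
}

#' Propagate pool magnetization under a rate matrix
#'
#' Solves `dM/dt = G M` by matrix exponential (eigendecomposition, with a
#' scaling-and-squaring fallback via [Matrix::expm()] when the eigenbasis
#' is ill-conditioned).  Serves as the oracle for all closed-form models.
#'
#' @param G Square generator matrix; off-diagonal entries must be
#'   non-negative.
#' @param initial Named (or plain) numeric vector of initial pool
#'   magnetizations, length `nrow(G)`.
#' @param delays Non-negative mixing times (s).
#' @return Matrix with one row per pool and one column per delay; row names
#'   are the pool labels, column names the delays.
#' @export
propagate_rate_matrix <- function(G, initial, delays) {
  G <- as.matrix(G)
  if (nrow(G) != ncol(G)) stop("rate matrix must be square")
  offdiag <- G; diag(offdiag) <- 0
  if (any(offdiag < 0)) stop("off-diagonal transfer rates must be >= 0")
  if (length(initial) != nrow(G))
    stop(sprintf("initial state has %d pools but the matrix has %d",
                 length(initial), nrow(G)))
  if (any(!is.finite(initial))) stop("initial magnetization must be finite")
  delays <- as.numeric(delays)
  if (any(!is.finite(delays)) || any(delays < 0)) {
    bad <- which(!is.finite(delays) | delays < 0)[1]
    stop(sprintf("delay at index %d is negative or non-finite", bad))
  }
  pools <- rownames(G)
  if (is.null(pools)) pools <- names(initial)
  if (is.null(pools)) pools <- paste0("pool", seq_len(nrow(G)))

  M <- .propagate(G, as.numeric(initial), delays)
  dimnames(M) <- list(pools, signif(delays, 10))
  M
}

# eigendecomposition propagation with expm fallback
.propagate <- function(G, m0, delays) {
  n <- nrow(G)
  ev <- tryCatch(eigen(G), error = function(e) NULL)
  coef <- NULL
  if (!is.null(ev)) {
    Vinv <- tryCatch(solve(ev$vectors), error = function(e) NULL)
    if (!is.null(Vinv)) {
      # crude condition estimate; a defective eigenbasis forces the fallback
      kappa <- max(Mod(ev$vectors)) * max(Mod(Vinv)) * n
      if (is.finite(kappa) && kappa < 1e10) coef <- Vinv %*% m0
    }
  }
  if (!is.null(coef)) {
    M <- vapply(delays, function(t)
      Re(ev$vectors %*% (exp(ev$values * t) * coef))[, 1], numeric(n))
  } else {
    M <- vapply(delays, function(t)
      as.numeric(Matrix::expm(G * t) %*% m0), numeric(n))
  }
  matrix(M, nrow = n)
}

#' Simulate z-z exchange peak volumes for a two-site system
#'
#' Closed-form solution for longitudinal magnetization starting entirely on
#' one site, with shared relaxation `R1`.  For magnetization of amplitude
#' `V0` starting on the major site A:
#' `V_AA(t) = V0 (p_A + p_B exp(-k_ex t)) exp(-R1 t)` and
#' `V_aA(t) = V0 p_B (1 - exp(-k_ex t)) exp(-R1 t)`; the minor-origin
#' curves are symmetric.  Peak labels are detected-site then origin-site,
#' so `aA` is the exchange cross peak from major-site origin.
#'
#' @param system An [exchange_system()].
#' @param delays Non-negative mixing times (s).
#' @param initial_site Optional origin site label; when given only that
#'   origin's auto and cross curve are returned, otherwise all four.
#' @param V0 Initial amplitude per origin (a.u.).
#' @return Named list of [volume_series()] (four, or two when
#'   `initial_site` is given).
#' @export
simulate_two_site <- function(system, delays, initial_site = NULL, V0 = 1) {
  stopifnot(inherits(system, "exchange_system"))
  delays <- as.numeric(delays)
  if (any(!is.finite(delays)) || any(delays < 0)) {
    bad <- which(!is.finite(delays) | delays < 0)[1]
    stop(sprintf("delay at index %d is negative or non-finite", bad))
  }
  A <- system$label_major; a <- system$label_minor
  kex <- system$k_ex; decay <- exp(-system$R1 * delays)
  if (kex > 0) {
    p <- populations(system); pA <- p[["p_major"]]; pB <- p[["p_minor"]]
    e <- exp(-kex * delays)
    vAA <- V0 * (pA + pB * e) * decay
    vaA <- V0 * pB * (1 - e) * decay
    vaa <- V0 * (pB + pA * e) * decay
    vAa <- V0 * pA * (1 - e) * decay
  } else {
    vAA <- vaa <- V0 * decay
    vaA <- vAa <- rep(0, length(delays))
  }
  out <- list(
    volume_series(paste0(A, A), delays, vAA),
    volume_series(paste0(a, A), delays, vaA),
    volume_series(paste0(a, a), delays, vaa),
    volume_series(paste0(A, a), delays, vAa))
  names(out) <- vapply(out, function(s) s$label[1], character(1))
  if (!is.null(initial_site)) {
    if (!initial_site %in% c(A, a))
      stop(sprintf("unknown site '%s'; sites are '%s' and '%s'",
                   initial_site, A, a))
    keep <- substr(names(out), 2, 2) == initial_site
    out <- out[keep]
  }
  out
}

#' Simulate the amide/amine z-z exchange scheme
#'
#' Two-pool scheme for an NH2 group (major conformer) exchanging with an NH
#' group (minor conformer).  On minor -> major conversion the NH proton is
#' converted equally to both NH2 protons, so that branch conserves pool
#' magnetization; on major -> minor conversion only a fraction
#' `retention_factor` of the NH2-pool magnetization is carried into NH
#' (default 1/2: one of the two amine protons is lost).  All pools share
#' `R1`.  With `retention_factor = 1` the scheme reduces to
#' [simulate_two_site()].
#'
#' Labels: `NH2` and `NH` are the auto peaks; `NH2'` (detected on NH2,
#' originating from NH) and `NH'` (detected on NH, from NH2) are the
#' exchange peaks.
#'
#' @param system An [exchange_system()].
#' @param delays Non-negative mixing times (s).
#' @param retention_factor Fraction in `[0, 1]` of NH2 magnetization
#'   retained on conversion to NH.
#' @param V0 Initial amplitude per origin (a.u.).
#' @return Named list of four [volume_series()]: `NH2`, `NH`, `NH2'`, `NH'`.
#' @export
simulate_nh2_nh_zz <- function(system, delays, retention_factor = 0.5,
                               V0 = 1) {
  stopifnot(inherits(system, "exchange_system"))
  G <- rate_matrix_two_site(system, retention_factor)
  from_nh2 <- propagate_rate_matrix(G, c(V0, 0), delays)
  from_nh <- propagate_rate_matrix(G, c(0, V0), delays)
  list(
    "NH2" = volume_series("NH2", delays, from_nh2[1, ]),
    "NH" = volume_series("NH", delays, from_nh[2, ]),
    "NH2'" = volume_series("NH2'", delays, from_nh[1, ]),
    "NH'" = volume_series("NH'", delays, from_nh2[2, ]))
}

#' Simulate exchange and NOE cross peaks of a four-pool system
#'
#' Propagates the 4x4 generator of [rate_matrix_noe_pair()] and reports the
#' eight curves detected on proton X (pools `A`/`a`) from all four origins.
#' Labels are detected-site then origin-site: `AA`, `aa` diagonal; `Aa`,
#' `aA` exchange cross peaks; `AB`, `ab` direct NOE cross peaks; `Ab`, `aB`
#' exchange-mediated NOE cross peaks.
#'
#' @param pair A [noe_pair_system()].
#' @param delays Non-negative mixing times (s).
#' @param origin_amplitudes Initial magnetization per origin pool
#'   `(A, a, B, b)`.  The default `"equilibrium"` uses the equilibrium
#'   populations `(p_major, p_minor, p_major, p_minor)` as in a NOESY
#'   experiment; a numeric vector of length 4 overrides it.
#' @return Named list of eight [volume_series()].
#' @export
simulate_exchange_noe <- function(pair, delays,
                                  origin_amplitudes = "equilibrium") {
  stopifnot(inherits(pair, "noe_pair_system"))
  G <- rate_matrix_noe_pair(pair)
  amp <- origin_amplitudes
  if (identical(amp, "equilibrium")) {
    ex <- pair$exchange
    amp <- if (ex$k_ex > 0) {
      p <- populations(ex)
      c(p[["p_major"]], p[["p_minor"]], p[["p_major"]], p[["p_minor"]])
    } else c(0.5, 0.5, 0.5, 0.5)
  }
  if (!is.numeric(amp) || length(amp) != 4L)
    stop("'origin_amplitudes' must be \"equilibrium\" or a numeric vector of length 4")
  pools <- c("A", "a", "B", "b")
  out <- list()
  for (i in seq_along(pools)) {
    m0 <- numeric(4); m0[i] <- amp[i]
    M <- propagate_rate_matrix(G, m0, delays)
    for (det in c("A", "a")) {
      lab <- paste0(det, pools[i])
      out[[lab]] <- volume_series(lab, delays, M[det, ])
    }
  }
  out[c("AA", "aa", "Aa", "aA", "AB", "ab", "Ab", "aB")]
}
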