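# Least-squares inference of exchange kinetics from peak-volume series.
#
# All fits use bounded Levenberg-Marquardt (minpack.lm::nls.lm) with a small
# multi-start ladder over the total exchange rate to avoid local minima.
# Uncertainties come from the Gauss-Newton (Jacobian) approximation at the
# optimum; inverse-variance weights are used when the series carry volume
# uncertainties.

.kex_starts <- c(1, 10, 50)

# assemble an exchange_fit result object
.fit_result <- function(est, se, rss, n, converged, scales = NULL,
                        flags = character(0)) {
  structure(list(k1_hat = unname(est["k1"]), k_rev_hat = unname(est["k_rev"]),
                 R1_hat = unname(est["R1"]),
                 k_ex_hat = unname(est["k1"]) + unname(est["k_rev"]),
                 se = se, rss = rss, n = n, converged = converged,
                 scales = scales, flags = flags, estimates = est),
            class = "exchange_fit")
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat("Exchange-kinetics fit\n")
  est <- x$estimates
  for (nm in names(est)) {
    se <- if (!is.null(x$se) && nm %in% names(x$se)) x$se[[nm]] else NA_real_
    cat(sprintf("  %-8s %10.4g  +/- %.3g\n", nm, est[[nm]], se))
  }
  cat(sprintf("  k_ex = %.4g s^-1;  rss = %.4g over %d points;  %s\n",
              x$k_ex_hat, x$rss, x$n,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# run nls.lm over a start list, keep the best converged solution
.lm_multistart <- function(residual_fn, starts, lower, upper) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = residual_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  best
}

# Gauss-Newton standard errors from an nls.lm fit; NA on singularity
.lm_se <- function(fit, n_par) {
  n <- length(fit$fvec)
  dof <- max(n - n_par, 1)
  s2 <- fit$deviance / dof
  covm <- tryCatch(s2 * solve(fit$hessian / 2), error = function(e) NULL)
  if (is.null(covm)) return(rep(NA_real_, n_par))
  se <- sqrt(pmax(diag(covm), 0))
  names(se) <- names(fit$par)
  se
}

.weights_of <- function(series) {
  if ("sigma_volume" %in% names(series) && all(series$sigma_volume > 0))
    1 / series$sigma_volume else rep(1, nrow(series))
}

#' Global fit of the amide/amine z-z exchange curves
#'
#' Fits the four NH2/NH-scheme curves jointly with a single `(k1, k_rev,
#' R1)` shared by all curves (the model of [simulate_nh2_nh_zz()]) plus one
#' free initial amplitude per origin (NH2-origin and NH-origin).
#'
#' @param series Named list of [volume_series()] containing labels `NH2`,
#'   `NH`, `NH2'`, `NH'` on a common delay grid (>= 4 distinct delays).
#' @param retention_factor Retention fraction of the forward branch
#'   (default 1/2), held fixed during the fit.
#' @return An `exchange_fit` with `k1_hat`, `k_rev_hat`, `R1_hat`,
#'   standard errors, rss, and the two per-origin scale factors.
#' @export
fit_global_zz <- function(series, retention_factor = 0.5) {
  labs <- c("NH2", "NH", "NH2'", "NH'")
  if (is.null(names(series)))
    names(series) <- vapply(series, function(s) s$label[1], character(1))
  missing_lab <- setdiff(labs, names(series))
  if (length(missing_lab))
    stop(sprintf("missing curve label(s): %s",
                 paste(missing_lab, collapse = ", ")))
  series <- series[labs]
  delays <- series[["NH2"]]$t_mix_s
  if (length(unique(delays)) < 4L)
    stop("need at least 4 distinct delays per curve")
  for (s in series)
    if (!isTRUE(all.equal(s$t_mix_s, delays)))
      stop("all four curves must share the same delay grid")
  y <- unlist(lapply(series, function(s) s$volume), use.names = FALSE)
  w <- unlist(lapply(series, .weights_of), use.names = FALSE)
  n <- length(y)
  if (n < 6L) stop("fewer data points than free parameters")

  model <- function(p) {
    sys <- exchange_system(p[["k1"]], p[["k_rev"]], p[["R1"]])
    G <- rate_matrix_two_site(sys, retention_factor)
    f2 <- .propagate(G, c(p[["c_nh2"]], 0), delays)   # NH2 origin
    f1 <- .propagate(G, c(0, p[["c_nh"]]), delays)    # NH origin
    c(f2[1, ], f1[2, ], f1[1, ], f2[2, ])             # NH2, NH, NH2', NH'
  }
  resid_fn <- function(p) w * (model(p) - y)

  amp0 <- max(abs(y), 1e-12)
  starts <- lapply(.kex_starts, function(kex)
    c(k1 = kex / 3, k_rev = 2 * kex / 3, R1 = 2, c_nh2 = amp0, c_nh = amp0))
  fit <- .lm_multistart(resid_fn, starts,
                        lower = c(0, 0, 0, 0, 0),
                        upper = rep(Inf, 5))
  if (is.null(fit)) {
    est <- c(k1 = NA_real_, k_rev = NA_real_, R1 = NA_real_)
    return(.fit_result(est, NULL, NA_real_, n, FALSE,
                       flags = "optimizer failed"))
  }
  est <- fit$par
  se <- .lm_se(fit, length(est))
  converged <- fit$info %in% 1:4
  flags <- if (converged) character(0) else "non-convergence"
  .fit_result(est[c("k1", "k_rev", "R1")], se, fit$deviance, n, converged,
              scales = est[c("c_nh2", "c_nh")], flags = flags)
}

#' Fit an exchange cross-peak build-up curve for the total exchange rate
#'
#' Model: `V(t) = C (1 - exp(-k_ex t)) exp(-R1 t)` — build-up by exchange,
#' late decay by auto-relaxation.  The curve maximum sits at
#' `t* = log(1 + k_ex/R1) / k_ex`.
#'
#' @param series One exchange-cross-peak [volume_series()] with >= 5 points
#'   spanning both build-up and decay.
#' @return An `exchange_fit`; `k_ex_hat` carries the total rate, individual
#'   rates are `NA`.  Monotone non-decreasing data are flagged
#'   `"unconstrained R1"`; an all-zero curve is flagged unidentifiable.
#' @export
fit_buildup_sum <- function(series) {
  stopifnot(inherits(series, "volume_series"))
  t <- series$t_mix_s; y <- series$volume; w <- .weights_of(series)
  if (length(t) < 5L) stop("need at least 5 points")
  flags <- character(0)
  if (all(abs(y) < 1e-12 * max(1, max(abs(y))))) {
    est <- c(k1 = NA_real_, k_rev = NA_real_, R1 = NA_real_,
             k_ex = NA_real_, C = 0)
    res <- .fit_result(est[c("k1", "k_rev", "R1")], NULL, 0, length(t), FALSE,
                       flags = "unidentifiable: all-zero curve")
    res$k_ex_hat <- NA_real_
    res$estimates <- est
    return(res)
  }
  if (all(diff(y) >= -1e-9 * max(abs(y))))
    flags <- c(flags, "unconstrained R1: no decay observed")

  model <- function(p) p[["C"]] * (1 - exp(-p[["k_ex"]] * t)) *
    exp(-p[["R1"]] * t)
  resid_fn <- function(p) w * (model(p) - y)
  amp0 <- max(abs(y))
  starts <- lapply(.kex_starts, function(kex)
    c(k_ex = kex, R1 = 2, C = amp0))
  fit <- .lm_multistart(resid_fn, starts, lower = c(0, 0, -Inf),
                        upper = c(Inf, Inf, Inf))
  if (is.null(fit))
    stop("build-up fit failed to run")
  se <- .lm_se(fit, 3L)
  converged <- fit$info %in% 1:4
  est <- c(k1 = NA_real_, k_rev = NA_real_, R1 = unname(fit$par["R1"]),
           k_ex = unname(fit$par["k_ex"]), C = unname(fit$par["C"]))
  res <- .fit_result(est[c("k1", "k_rev", "R1")], se, fit$deviance,
                     length(t), converged, flags = flags)
  res$k_ex_hat <- est[["k_ex"]]
  res$estimates <- est
  res
}

#' Fit normalized exchange cross peaks for the individual rate constants
#'
#' The cross peak is normalized by the matching diagonal,
#' `r(t) = cross / (diagonal + cross)`, which removes relaxation and
#' amplitude and follows `r(t) = p (1 - exp(-k_ex t))`, where `p` is the
#' equilibrium population of the destination conformer.  The rate into that
#' conformer is `p * k_ex` and the complementary rate is `k_ex - p * k_ex`.
#' For the usual case (`aA` normalized by `AA + aA`) the destination is the
#' minor conformer, so `k1 = p * k_ex` and `k_rev = k_ex - k1`.
#'
#' @param cross Exchange-cross-peak [volume_series()].
#' @param diagonal Matching diagonal-peak [volume_series()] on the same
#'   delay grid.
#' @return An `exchange_fit` with separated `k1_hat`, `k_rev_hat` and the
#'   fitted population in `estimates["p_dest"]`.  `R1_hat` is `NA` (it
#'   cancels in the ratio).
#' @export
fit_normalized_rates <- function(cross, diagonal) {
  stopifnot(inherits(cross, "volume_series"),
            inherits(diagonal, "volume_series"))
  if (!isTRUE(all.equal(cross$t_mix_s, diagonal$t_mix_s)))
    stop("cross and diagonal series must share the same delay grid")
  t <- cross$t_mix_s
  denom <- cross$volume + diagonal$volume
  if (any(abs(denom) < .Machine$double.eps))
    stop("diagonal + cross volume is zero at some delays; ratio undefined")
  r <- cross$volume / denom
  if (any(r < -0.05) || any(r > 1.05))
    warning("normalized ratio outside [0, 1] beyond noise tolerance")

  model <- function(p) p[["p_dest"]] * (1 - exp(-p[["k_ex"]] * t))
  resid_fn <- function(p) model(p) - r
  starts <- lapply(.kex_starts, function(kex)
    c(p_dest = max(min(max(r), 0.95), 0.05), k_ex = kex))
  fit <- .lm_multistart(resid_fn, starts, lower = c(0, 0), upper = c(1, Inf))
  if (is.null(fit)) stop("normalized-ratio fit failed to run")
  p_dest <- unname(fit$par["p_dest"]); kex <- unname(fit$par["k_ex"])
  se <- .lm_se(fit, 2L)
  # delta-method errors for the derived rates
  covm <- tryCatch((fit$deviance / max(length(t) - 2, 1)) *
                     solve(fit$hessian / 2), error = function(e) NULL)
  se_rates <- c(k1 = NA_real_, k_rev = NA_real_)
  if (!is.null(covm)) {
    gk1 <- c(kex, p_dest)                 # d(p*kex)/d(p, kex)
    gkr <- c(-kex, 1 - p_dest)
    se_rates["k1"] <- sqrt(max(t(gk1) %*% covm %*% gk1, 0))
    se_rates["k_rev"] <- sqrt(max(t(gkr) %*% covm %*% gkr, 0))
  }
  est <- c(k1 = p_dest * kex, k_rev = (1 - p_dest) * kex, R1 = NA_real_,
           p_dest = p_dest, k_ex = kex)
  converged <- fit$info %in% 1:4
  res <- .fit_result(est[c("k1", "k_rev", "R1")],
                     c(se_rates, se), fit$deviance, length(t), converged)
  res$k_ex_hat <- kex
  res$estimates <- est
  res
}

#' Fit exchange-mediated NOE ratio curves for the individual rates
#'
#' The exchange-mediated cross peak is divided by the sum with its direct
#' NOE partner, `q(t) = mediated / (direct + mediated)` (e.g. `Ab / (AB +
#' Ab)`).  Because every pool shares `R1`, the relaxation factor cancels
#' and the ratio depends only on `(k1, k_rev, sigma)`.  The ratio is fit to
#' the exact four-pool rate-matrix model with equilibrium origin
#' amplitudes.
#'
#' @param mediated Exchange-mediated [volume_series()] (label `Ab` or `aB`).
#' @param direct Direct-NOE partner [volume_series()] (`AB` or `ab`) on the
#'   same delay grid.
#' @param sigma Fixed shared cross-relaxation rate (s^-1; default -1).
#'   Because the shared-rate ratio is invariant to the magnitude of
#'   `sigma` (the NOE step scales mediated and direct transfer
#'   identically), it is held fixed rather than estimated; `NULL` adds it
#'   to the fit as a diagnostic only.
#' @return An `exchange_fit` with `k1_hat`, `k_rev_hat` and the fitted
#'   `|sigma|` in `estimates["sigma"]`.
#' @export
fit_mediated_noe <- function(mediated, direct, sigma = -1) {
  stopifnot(inherits(mediated, "volume_series"),
            inherits(direct, "volume_series"))
  if (!isTRUE(all.equal(mediated$t_mix_s, direct$t_mix_s)))
    stop("mediated and direct series must share the same delay grid")
  t <- mediated$t_mix_s
  if (max(abs(mediated$volume)) < 1e-12 * max(1, max(abs(direct$volume)))) {
    est <- c(k1 = 0, k_rev = NA_real_, R1 = NA_real_, sigma = NA_real_)
    return(.fit_result(est[c("k1", "k_rev", "R1")], NULL, 0, length(t),
                       FALSE, flags = "unidentifiable: no mediated signal"))
  }
  denom <- mediated$volume + direct$volume
  keep <- abs(denom) > .Machine$double.eps
  if (sum(keep) < 4L) {
    est <- c(k1 = NA_real_, k_rev = NA_real_, R1 = NA_real_,
             sigma = NA_real_)
    return(.fit_result(est[c("k1", "k_rev", "R1")], NULL, NA_real_,
                       length(t), FALSE,
                       flags = "unidentifiable: direct + mediated volume is zero"))
  }
  q <- mediated$volume[keep] / denom[keep]
  tq <- t[keep]

  # label orientation: for Ab/(AB+Ab) the ratio is computed in the A row;
  # for aB/(ab+aB) in the a row.  Infer from the label's detected site.
  det <- substr(normalize_primes(mediated$label[1]), 1, 1)
  med_lab <- if (det == "A") "Ab" else "aB"
  dir_lab <- if (det == "A") "AB" else "ab"

  model_ratio <- function(k1, k_rev, sig) {
    sys <- exchange_system(k1, k_rev, R1 = 0)
    pr <- noe_pair_system(sys, sigma_major = -abs(sig))
    cur <- simulate_exchange_noe(pr, tq)
    m <- cur[[med_lab]]$volume; d <- cur[[dir_lab]]$volume
    dn <- m + d
    dn[abs(dn) < .Machine$double.eps] <- NA_real_
    m / dn
  }
  resid_fn <- function(p) {
    sig <- if (is.null(sigma)) p[["sigma"]] else abs(sigma)
    pred <- model_ratio(p[["k1"]], p[["k_rev"]], sig)
    res <- pred - q
    res[!is.finite(res)] <- 0
    res
  }
  starts <- lapply(.kex_starts, function(kex) {
    st <- c(k1 = kex / 3, k_rev = 2 * kex / 3)
    if (is.null(sigma)) st <- c(st, sigma = 1)
    st
  })
  n_par <- if (is.null(sigma)) 3L else 2L
  fit <- .lm_multistart(resid_fn, starts,
                        lower = c(1e-6, 1e-6, if (is.null(sigma)) 1e-4),
                        upper = rep(Inf, n_par))
  if (is.null(fit)) stop("mediated-NOE fit failed to run")
  se <- .lm_se(fit, n_par)
  sig_hat <- if (is.null(sigma)) unname(fit$par["sigma"]) else abs(sigma)
  est <- c(k1 = unname(fit$par["k1"]), k_rev = unname(fit$par["k_rev"]),
           R1 = NA_real_, sigma = sig_hat)
  converged <- fit$info %in% 1:4
  res <- .fit_result(est[c("k1", "k_rev", "R1")], se, fit$deviance,
                     length(tq), converged)
  res$estimates <- est
  res
}

#' Aggregate per-site exchange fits
#'
#' Unweighted mean and sample standard deviation of each rate parameter
#' over the converged fits, as used to summarize results from several
#' reporter sites.
#'
#' @param results List of `exchange_fit` objects (>= 2 converged).
#' @return List with `mean`, `sd` (named vectors over `k1`, `k_rev`, `R1`,
#'   `k_ex`), `n_used` and `n_dropped` (non-converged entries excluded).
#' @export
aggregate_sites <- function(results) {
  if (!length(results)) stop("no fit results supplied")
  stopifnot(all(vapply(results, inherits, logical(1), "exchange_fit")))
  ok <- vapply(results, function(r) isTRUE(r$converged), logical(1))
  used <- results[ok]
  if (length(used) < 2L)
    stop("need at least 2 converged results to aggregate")
  grab <- function(f) vapply(used, f, numeric(1))
  mat <- rbind(k1 = grab(function(r) r$k1_hat),
               k_rev = grab(function(r) r$k_rev_hat),
               R1 = grab(function(r) r$R1_hat),
               k_ex = grab(function(r) r$k_ex_hat))
  list(mean = apply(mat, 1, mean, na.rm = TRUE),
       sd = apply(mat, 1, stats::sd, na.rm = TRUE),
       n_used = length(used), n_dropped = sum(!ok))
}
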