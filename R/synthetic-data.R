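# Synthetic datasets with the statistical structure the analyses assume:
# two-conformer exchange at a ~3:1 population ratio with rates of a few
# per second, shared R1, mixing times covering build-up and decay, and
# multiplicative Gaussian volume noise.

#' Scenario configuration for the synthetic generators
#'
#' Defaults emulate the studied system: forward/reverse rates 3.5/7.7 s^-1
#' for the local (amide/amine) scheme — use `k1 = 4.3, k_rev = 8.8` for the
#' global NOESY scheme — shared `R1 = 2 s^-1`, 16 log-spaced delays between
#' 0.01 and 0.5 s, and 5% multiplicative Gaussian noise.
#'
#' @param k1,k_rev,R1 Rate constants (s^-1).
#' @param sigma Cross-relaxation rate(s) for NOE scenarios (s^-1); recycled
#'   over sites.
#' @param retention_factor Forward-branch retention of the amide/amine
#'   scheme.
#' @param delays Mixing-time grid (s), strictly increasing.
#' @param noise_sd Multiplicative Gaussian noise fraction (>= 0).
#' @param n_sites Number of reporter sites to generate.
#' @param seed Mandatory RNG seed.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(k1 = 3.5, k_rev = 7.7, R1 = 2.0, sigma = -1.0,
                            retention_factor = 0.5,
                            delays = exp(seq(log(0.01), log(0.5),
                                             length.out = 16)),
                            noise_sd = 0.05, n_sites = 1, seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed))
    stop("'seed' is mandatory and must be a single number")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be >= 0")
  delays <- as.numeric(delays)
  if (any(delays < 0) || any(diff(delays) <= 0))
    stop("'delays' must be non-negative and strictly increasing")
  if (retention_factor < 0 || retention_factor > 1)
    stop("'retention_factor' must be in [0, 1]")
  if (n_sites < 1) stop("'n_sites' must be >= 1")
  structure(list(k1 = k1, k_rev = k_rev, R1 = R1, sigma = sigma,
                 retention_factor = retention_factor, delays = delays,
                 noise_sd = noise_sd, n_sites = as.integer(n_sites),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# multiplicative Gaussian noise; volumes never flip sign (truncated at
# 1e-6 of the clean signal)
.apply_noise <- function(v, sd_frac) {
  if (sd_frac == 0) return(v)
  noisy <- v * (1 + stats::rnorm(length(v), 0, sd_frac))
  floor_v <- 1e-6 * abs(v)
  ifelse(v > 0, pmax(noisy, floor_v), ifelse(v < 0, pmin(noisy, -floor_v), 0))
}

.truth_record <- function(config, extra = list()) {
  c(list(k1 = config$k1, k_rev = config$k_rev, R1 = config$R1,
         retention_factor = config$retention_factor,
         noise_sd = config$noise_sd, seed = config$seed), extra)
}

.write_truth <- function(truth, path) {
  writeLines(sprintf("%s\t%s", names(truth),
                     vapply(truth, function(v) paste(format(v, digits = 15),
                                                     collapse = ","),
                            character(1))),
             path)
  invisible(path)
}

#' Generate a synthetic z-z exchange dataset
#'
#' Four amide/amine-scheme curves per site from
#' [simulate_nh2_nh_zz()], with multiplicative Gaussian noise, plus a
#' ground-truth record.  Reproducible under the config seed.
#'
#' @param config A [scenario_config()].
#' @param dir Optional directory; when given, per-site TSVs
#'   (`zz_site<i>.tsv`) and a `ground_truth.tsv` sidecar are written.
#' @return List with `sites` (list of named series lists), `truth`, and
#'   `paths` when written.
#' @export
generate_zz_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  sys <- exchange_system(config$k1, config$k_rev, config$R1)
  sites <- lapply(seq_len(config$n_sites), function(i) {
    clean <- simulate_nh2_nh_zz(sys, config$delays,
                                config$retention_factor)
    lapply(clean, function(s) {
      volume_series(s$label[1], s$t_mix_s,
                    .apply_noise(s$volume, config$noise_sd))
    })
  })
  names(sites) <- paste0("site", seq_along(sites))
  truth <- .truth_record(config)
  out <- list(sites = sites, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(seq_along(sites), function(i) {
      p <- file.path(dir, sprintf("zz_site%d.tsv", i))
      write_volume_series(sites[[i]], p)
      p
    }, character(1))
    tp <- file.path(dir, "ground_truth.tsv")
    .write_truth(truth, tp)
    out$paths <- c(paths, tp)
  }
  out
}

#' Generate a synthetic NOESY exchange + NOE dataset
#'
#' Eight curves per site from [simulate_exchange_noe()] (diagonal,
#' exchange, direct NOE and exchange-mediated peaks), with per-site
#' cross-relaxation rates, noise, and a ground-truth record.
#'
#' @param config A [scenario_config()]; `sigma` is recycled over
#'   `n_sites`.
#' @param dir Optional output directory (`noesy_site<i>.tsv` +
#'   `ground_truth.tsv`).
#' @return As [generate_zz_dataset()].
#' @export
generate_noesy_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  sys <- exchange_system(config$k1, config$k_rev, config$R1)
  sig <- rep_len(config$sigma, config$n_sites)
  sites <- lapply(seq_len(config$n_sites), function(i) {
    pair <- noe_pair_system(sys, sigma_major = sig[i])
    clean <- simulate_exchange_noe(pair, config$delays)
    lapply(clean, function(s)
      volume_series(s$label[1], s$t_mix_s,
                    .apply_noise(s$volume, config$noise_sd)))
  })
  names(sites) <- paste0("site", seq_along(sites))
  truth <- .truth_record(config, list(sigma = sig))
  out <- list(sites = sites, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(seq_along(sites), function(i) {
      p <- file.path(dir, sprintf("noesy_site%d.tsv", i))
      write_volume_series(sites[[i]], p)
      p
    }, character(1))
    tp <- file.path(dir, "ground_truth.tsv")
    .write_truth(truth, tp)
    out$paths <- c(paths, tp)
  }
  out
}

#' Generate a synthetic NOE peak table
#'
#' Draws atom pairs over a duplex and distances from a given range, then
#' sets volumes by the inverse-sixth-power law against the reference pair,
#' optionally with lognormal noise.  The reference peak (pyrimidine H5-H6
#' at its fixed distance) is always included as the first row, so the
#' table is directly consumable by [calibrate_distances()].
#'
#' @param n_peaks Number of peaks including the reference.
#' @param n_residues Duplex length (residues).
#' @param seed RNG seed.
#' @param distance_range Distances are drawn uniformly from this range (A);
#'   must lie within [1.8, 7.0].
#' @param reference As in [calibrate_distances()].
#' @param noise_sd Lognormal sd of the volume noise (0 = noiseless).
#' @param v_ref Reference peak volume (a.u.).
#' @return List with `peaks` (a [noe_peaks()] table), `truth` (generating
#'   distances, first entry the reference).
#' @export
generate_noe_peak_table <- function(n_peaks, n_residues, seed,
                                    distance_range = c(1.9, 6.8),
                                    reference = list(res = 1, atom_i = "H5",
                                                     atom_j = "H6",
                                                     distance = 2.45),
                                    noise_sd = 0, v_ref = 1e6) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (n_peaks < 1 || n_residues < 1)
    stop("'n_peaks' and 'n_residues' must be >= 1")
  if (distance_range[1] < 1.8 || distance_range[2] > 7.0 ||
      distance_range[1] >= distance_range[2])
    stop("'distance_range' must be increasing and within [1.8, 7.0] A")
  set.seed(seed)
  n_free <- n_peaks - 1L
  atom_pool <- c("H1'", "H2'", "H2''", "H3'", "H4'", "H5", "H6", "H8",
                 "H41", "H42", "H3")
  res_i <- sample.int(n_residues, n_free, replace = TRUE)
  # duplex-like mix: mostly intra-nucleotide and sequential contacts,
  # a small long-range fraction
  offset <- sample(c(0L, 1L, 2L, 3L, 4L, 5L), n_free, replace = TRUE,
                   prob = c(0.32, 0.56, 0.04, 0.03, 0.03, 0.02))
  res_j <- pmin(pmax(res_i + offset, 1L), n_residues)
  dist <- stats::runif(n_free, distance_range[1], distance_range[2])
  vol <- v_ref * (reference$distance / dist)^6
  if (noise_sd > 0) vol <- vol * stats::rlnorm(n_free, 0, noise_sd)
  peaks <- noe_peaks(
    res_i = c(reference$res, res_i),
    atom_i = c(reference$atom_i, sample(atom_pool, n_free, replace = TRUE)),
    res_j = c(reference$res, res_j),
    atom_j = c(reference$atom_j, sample(atom_pool, n_free, replace = TRUE)),
    volume = c(v_ref, vol))
  list(peaks = peaks,
       truth = list(distances = c(reference$distance, dist), seed = seed))
}
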