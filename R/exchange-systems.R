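#' Two-site exchange system
#'
#' Defines a two-conformer kinetic model: a major species interconverting
#' with a minor species under shared longitudinal relaxation.  Rates are
#' first-order and the populations follow from detailed balance.
#'
#' @param k1 Forward rate constant, major -> minor (s^-1).
#' @param k_rev Reverse rate constant, minor -> major (s^-1).
#' @param R1 Shared longitudinal relaxation rate (s^-1).
#' @param label_major,label_minor Site names used in peak labels.
#'
#' @return An object of class `exchange_system` with fields `k1`, `k_rev`,
#'   `R1`, `label_major`, `label_minor` and derived `k_ex = k1 + k_rev`.
#'   Equilibrium populations are available through [populations()].
#'
#' @examples
#' sys <- exchange_system(k1 = 3.5, k_rev = 7.7, R1 = 2)
#' populations(sys)  # p_major = k_rev/k_ex, p_minor = k1/k_ex
#' @export
exchange_system <- function(k1, k_rev, R1, label_major = "A",
                            label_minor = "a") {
  for (nm in c("k1", "k_rev", "R1")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("'%s' must be a single finite non-negative number", nm))
  }
  k1 <- unname(k1); k_rev <- unname(k_rev); R1 <- unname(R1)
  structure(
    list(k1 = k1, k_rev = k_rev, R1 = R1, k_ex = k1 + k_rev,
         label_major = as.character(label_major),
         label_minor = as.character(label_minor)),
    class = "exchange_system")
}

#' Equilibrium populations of a two-site system
#'
#' @param system An [exchange_system()].
#' @return Named numeric vector `c(p_major, p_minor)`; they sum to 1.
#'   With `k1 = k_rev = 0` the stationary distribution is undefined and an
#'   error is raised.
#' @export
populations <- function(system) {
  stopifnot(inherits(system, "exchange_system"))
  if (system$k_ex <= 0)
    stop("populations are undefined: k1 + k_rev = 0 (no exchange)")
  c(p_major = system$k_rev / system$k_ex,
    p_minor = system$k1 / system$k_ex)
}

#' @export
print.exchange_system <- function(x, ...) {
  cat(sprintf("Two-site exchange system  [%s <-> %s]\n",
              x$label_major, x$label_minor))
  cat(sprintf("  k1 (major->minor): %.4g s^-1\n", x$k1))
  cat(sprintf("  k_rev (minor->major): %.4g s^-1\n", x$k_rev))
  cat(sprintf("  R1: %.4g s^-1   k_ex: %.4g s^-1\n", x$R1, x$k_ex))
  if (x$k_ex > 0) {
    p <- populations(x)
    cat(sprintf("  populations: p_major = %.3f, p_minor = %.3f\n",
                p[1], p[2]))
  }
  invisible(x)
}

#' Four-pool exchange + NOE system
#'
#' Two protons (X, Y) in each of two interconverting conformers.  Chemical
#' exchange connects the same proton across conformers; dipolar
#' cross-relaxation connects the two protons within a conformer.  Pool
#' labels are `A`/`a` for proton X in the major/minor conformer and `B`/`b`
#' for proton Y.
#'
#' @param exchange An [exchange_system()] shared by both protons.
#' @param sigma_major Cross-relaxation rate between X and Y within the major
#'   conformer (s^-1).  The sign follows the usual NOE convention (negative
#'   for slowly tumbling macromolecules); the magnitude sets the transfer
#'   rate in the kinetic matrix.
#' @param sigma_minor Same for the minor conformer.
#' @return Object of class `noe_pair_system`.
#' @export
noe_pair_system <- function(exchange, sigma_major, sigma_minor = sigma_major) {
  stopifnot(inherits(exchange, "exchange_system"))
  for (nm in c("sigma_major", "sigma_minor")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm))
  }
  structure(list(exchange = exchange, sigma_major = sigma_major,
                 sigma_minor = sigma_minor),
            class = "noe_pair_system")
}

#' @export
print.noe_pair_system <- function(x, ...) {
  cat("Four-pool exchange + NOE system\n")
  print(x$exchange)
  cat(sprintf("  sigma_major: %.4g s^-1, sigma_minor: %.4g s^-1\n",
              x$sigma_major, x$sigma_minor))
  invisible(x)
}

# Peak labels understood by the volume-series container.  Two-letter labels
# follow the detected/origin convention for exchange and NOE cross peaks;
# the amide/amine scheme uses NH2/NH with primes for exchange peaks.
.peak_alphabet <- c(
  outer(c("A", "a", "B", "b"), c("A", "a", "B", "b"), paste0),
  "NH2", "NH", "NH2'", "NH'")

#' Labelled peak-volume vs mixing-time series
#'
#' @param label Peak label from the declared alphabet (e.g. `"AA"`, `"aA"`,
#'   `"NH2'"`).  Unicode primes are normalized to ASCII.
#' @param t_mix Mixing times (s), strictly increasing and non-negative.
#' @param volume Peak volumes (arbitrary units), one per mixing time.
#' @param sigma_volume Optional volume uncertainties (same length).
#' @return A `volume_series` object (also a data.frame with columns
#'   `label`, `t_mix_s`, `volume` and optionally `sigma_volume`).
#' @export
volume_series <- function(label, t_mix, volume, sigma_volume = NULL) {
  label <- normalize_primes(as.character(label))
  if (length(label) != 1L || !(label %in% .peak_alphabet))
    stop(sprintf("unknown peak label '%s'; expected one of: %s", label,
                 paste(.peak_alphabet, collapse = ", ")))
  t_mix <- as.numeric(t_mix); volume <- as.numeric(volume)
  if (length(t_mix) != length(volume))
    stop("'t_mix' and 'volume' must have equal length")
  if (any(!is.finite(t_mix)) || any(t_mix < 0)) {
    bad <- which(!is.finite(t_mix) | t_mix < 0)[1]
    stop(sprintf("mixing time at index %d is negative or non-finite", bad))
  }
  if (length(t_mix) > 1L && any(diff(t_mix) <= 0))
    stop("mixing times must be strictly increasing")
  if (any(!is.finite(volume))) stop("volumes must be finite")
  df <- data.frame(label = label, t_mix_s = t_mix, volume = volume,
                   stringsAsFactors = FALSE)
  if (!is.null(sigma_volume)) {
    sigma_volume <- as.numeric(sigma_volume)
    if (length(sigma_volume) != length(t_mix))
      stop("'sigma_volume' must match the number of mixing times")
    if (any(!is.finite(sigma_volume)) || any(sigma_volume < 0))
      stop("'sigma_volume' must be finite and non-negative")
    df$sigma_volume <- sigma_volume
  }
  class(df) <- c("volume_series", "data.frame")
  df
}

# ASCII-fold typographic primes (and PDB '*' prime dialect).
normalize_primes <- function(x) {
  x <- gsub("′", "'", x)
  x <- gsub("’", "'", x)
  gsub("*", "'", x, fixed = TRUE)
}

#' Write volume series to a TSV file
#'
#' One or more series are stacked into a single table with columns `label`,
#' `t_mix_s`, `volume` and, when any series carries uncertainties,
#' `sigma_volume`.
#'
#' @param series A `volume_series` or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_volume_series <- function(series, path) {
  if (inherits(series, "volume_series")) series <- list(series)
  stopifnot(all(vapply(series, inherits, logical(1), "volume_series")))
  has_sigma <- any(vapply(series, function(s) "sigma_volume" %in% names(s),
                          logical(1)))
  rows <- lapply(series, function(s) {
    df <- as.data.frame(s)
    if (has_sigma && !"sigma_volume" %in% names(df)) df$sigma_volume <- NA_real_
    df
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read volume series from a TSV file
#'
#' @param path File written by [write_volume_series()] (columns `label`,
#'   `t_mix_s`, `volume`, optional `sigma_volume`).  A missing uncertainty
#'   column yields unweighted series.
#' @return Named list of `volume_series`, one per distinct label.
#' @export
read_volume_series <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("label", "t_mix_s", "volume")
  if (!all(need %in% names(df)))
    stop(sprintf("missing required columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  out <- lapply(split(df, df$label), function(d) {
    d <- d[order(d$t_mix_s), , drop = FALSE]
    sig <- if ("sigma_volume" %in% names(d) && !anyNA(d$sigma_volume))
      d$sigma_volume else NULL
    volume_series(d$label[1], d$t_mix_s, d$volume, sig)
  })
  out[order(names(out))]
}
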