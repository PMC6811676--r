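# Karplus-equation conversion between three-bond scalar couplings and
# dihedral angles, with optional electronegativity correction terms.

#' Karplus parameter set
#'
#' Coefficients of the three-bond coupling relation
#' `J(phi) = A cos^2(phi) + B cos(phi) + C`, optionally extended with
#' substituent electronegativity corrections in the generalized
#' (Haasnoot-type) form
#' `J(phi) = P1 cos^2(phi) + P2 cos(phi) + P3 +
#'   sum_i lambda_i (P4 + P5 cos^2(xi_i phi + P6 |lambda_i|))`,
#' where `lambda_i` is the (beta-corrected) group electronegativity of
#' substituent i and `xi_i = +/-1` encodes its orientation.
#'
#' @param A,B,C Coefficients of the plain three-term form (Hz).  `A` must
#'   be positive.
#' @param corrections Optional data.frame with columns `lambda` and `xi`
#'   (one row per non-hydrogen substituent) activating the generalized
#'   form; `A`, `B`, `C` then play the role of `P1`, `P2`, `P3`.
#' @param P4,P5,P6 Correction-term constants (Hz, Hz, degrees).
#' @return Object of class `karplus_params`.
#' @seealso [karplus_params_h1h2()] for the bundled sugar parameterization.
#' @export
karplus_params <- function(A, B, C, corrections = NULL,
                           P4 = 0.56, P5 = -2.47, P6 = 16.9) {
  if (!is.numeric(A) || A <= 0) stop("'A' must be positive")
  stopifnot(is.numeric(B), is.numeric(C))
  if (!is.null(corrections)) {
    if (!is.data.frame(corrections) ||
        !all(c("lambda", "xi") %in% names(corrections)))
      stop("'corrections' needs columns 'lambda' and 'xi'")
    if (!all(corrections$xi %in% c(-1, 1)))
      stop("'xi' entries must be +1 or -1")
  }
  structure(list(A = A, B = B, C = C, corrections = corrections,
                 P4 = P4, P5 = P5, P6 = P6),
            class = "karplus_params")
}

#' Default H1'-H2' Karplus parameterization for 2'-deoxyribose
#'
#' Generalized (electronegativity-corrected) Karplus relation for the
#' H1'-C1'-C2'-H2' coupling with the standard substituent set of a
#' 2'-deoxyribose nucleotide: the ring oxygen O4' and the glycosidic
#' nitrogen on C1', and C3' on C2' (the geminal H2'' contributes no
#' correction).  Group electronegativities carry the beta-substituent
#' correction.  The parameterization reproduces the characteristic ~1 Hz
#' (N-type) to ~10 Hz (S-type) range of sugar H1'-H2' couplings.
#'
#' @return A [karplus_params()] object.
#' @export
karplus_params_h1h2 <- function() {
  karplus_params(
    A = 13.70, B = -0.73, C = 0,
    corrections = data.frame(
      substituent = c("O4'", "N-base", "C3'"),
      lambda = c(1.27 - 0.14 * 0.45,          # O4', beta C4'
                 0.85 - 0.14 * (0.45 + 0.45), # base N, beta 2x C
                 0.45 - 0.14 * (1.27 + 0.45)),# C3', beta O3' + C4'
      xi = c(+1, -1, +1)))
}

#' Evaluate a Karplus relation
#'
#' @param phi Dihedral angle(s), degrees.
#' @param params A [karplus_params()]; default [karplus_params_h1h2()].
#' @return Coupling constant(s) J in Hz (vectorized over `phi`).
#' @examples
#' karplus_forward(90, karplus_params(10.2, -0.8, 0))  # = C = 0
#' @export
karplus_forward <- function(phi, params = karplus_params_h1h2()) {
  stopifnot(inherits(params, "karplus_params"))
  d <- pi / 180
  cphi <- cos(phi * d)
  J <- params$A * cphi^2 + params$B * cphi + params$C
  if (!is.null(params$corrections)) {
    for (i in seq_len(nrow(params$corrections))) {
      lam <- params$corrections$lambda[i]
      xi <- params$corrections$xi[i]
      J <- J + lam * (params$P4 + params$P5 *
                        cos((xi * phi + params$P6 * abs(lam)) * d)^2)
    }
  }
  J
}

#' Invert a Karplus relation
#'
#' Finds all dihedral angles on `[0, 360)` (or within a branch window) at
#' which the Karplus curve takes the value `J`, by bracketed root finding
#' on a 1-degree grid refined to 1e-6 degrees.
#'
#' @param J Observed coupling (Hz).
#' @param params A [karplus_params()].
#' @param branch Optional angular window `c(lo, hi)` in degrees; only roots
#'   inside it are returned.
#' @return Numeric vector of solutions phi (degrees), sorted.
#' @examples
#' karplus_invert(6.5, branch = c(90, 180))  # ~142 for the sugar default
#' @export
karplus_invert <- function(J, params = karplus_params_h1h2(),
                           branch = c(0, 360)) {
  stopifnot(inherits(params, "karplus_params"), length(J) == 1L,
            is.finite(J))
  if (length(branch) != 2L || branch[1] >= branch[2])
    stop("'branch' must be c(lo, hi) with lo < hi")
  grid <- seq(0, 360, by = 1)
  Jg <- karplus_forward(grid, params)
  fwd <- function(phi) karplus_forward(phi, params)
  f <- function(phi) fwd(phi) - J

  # true attainable range: refine the grid extremes through the continuous
  # curve (a grid extremum can undershoot the true one by ~1e-3 Hz)
  refine <- function(i, maximum) {
    lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
    stats::optimize(fwd, c(lo, hi), maximum = maximum)
  }
  jmax <- refine(which.max(Jg), TRUE)
  jmin <- refine(which.min(Jg), FALSE)
  if (J < jmin$objective - 1e-9 || J > jmax$objective + 1e-9)
    stop(sprintf(
      "J = %.4g Hz is outside the attainable range [%.4g, %.4g] Hz",
      J, jmin$objective, jmax$objective))

  fg <- Jg - J
  roots <- numeric(0)
  for (i in seq_len(length(grid) - 1)) {
    if (fg[i] == 0) roots <- c(roots, grid[i])
    if (fg[i] * fg[i + 1] < 0)
      roots <- c(roots, stats::uniroot(f, c(grid[i], grid[i + 1]),
                                       tol = 1e-6)$root)
  }
  if (fg[length(grid)] == 0) roots <- c(roots, 360)
  # tangent roots: J between a grid extremum and the true local extremum,
  # leaving no sign change on the grid.  Bracket through the refined
  # extremum on both sides.
  is_max <- c(FALSE, diff(sign(diff(fg))) < 0, FALSE)
  is_min <- c(FALSE, diff(sign(diff(fg))) > 0, FALSE)
  for (i in which((is_max & fg < 0) | (is_min & fg > 0))) {
    ex <- refine(i, maximum = fg[i] < 0)
    x0 <- ex[[1]]; f0 <- ex$objective - J
    if (abs(f0) < 1e-9) {
      roots <- c(roots, x0)
    } else if (f0 * fg[i] < 0) {
      lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
      roots <- c(roots, stats::uniroot(f, c(lo, x0), tol = 1e-6)$root,
                 stats::uniroot(f, c(x0, hi), tol = 1e-6)$root)
    }
  }
  roots <- sort(unique(round(roots %% 360, 6)))
  roots[roots >= branch[1] & roots <= branch[2]]
}
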