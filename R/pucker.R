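# Sugar-ring pseudorotation analysis (Altona-Sundaralingam convention).
#
# The five endocyclic torsions nu0..nu4 of a furanose ring are summarized
# by a pseudorotation phase P and a maximum puckering amplitude nu_max,
# with nu_j = nu_max * cos(P + 144 (j - 2)) so that nu2 = nu_max cos(P).

#' Endocyclic ring torsions
#'
#' @param nu Numeric vector of the five endocyclic torsions `nu0..nu4` in
#'   degrees, in the standard order `nu0 (C4'-O4'-C1'-C2')` through
#'   `nu4 (C3'-C4'-O4'-C1')`.  Each must lie in `(-180, 180]`.
#' @return Object of class `ring_torsions` (a named numeric vector).
#' @export
ring_torsions <- function(nu) {
  nu <- as.numeric(nu)
  if (length(nu) != 5L) stop("exactly five endocyclic torsions required")
  if (any(!is.finite(nu)) || any(nu <= -180) || any(nu > 180))
    stop("torsions must be finite and in (-180, 180] degrees")
  names(nu) <- paste0("nu", 0:4)
  structure(nu, class = "ring_torsions")
}

# Twenty 18-degree sectors of the pseudorotation wheel, half-open [lo, hi),
# centred at multiples of 18 degrees.  Envelope forms sit at odd multiples
# (C3'-endo at 18, O4'-endo at 90, C2'-endo at 162, ...); twist forms at
# even multiples are named by their two dominant displacements.
.pucker_wheel <- c(
  "C3'-endo/C2'-exo",  # P =   0
  "C3'-endo",          # P =  18
  "C3'-endo/C4'-exo",  # P =  36
  "C4'-exo",           # P =  54
  "O4'-endo/C4'-exo",  # P =  72
  "O4'-endo",          # P =  90
  "O4'-endo/C1'-exo",  # P = 108
  "C1'-exo",           # P = 126
  "C2'-endo/C1'-exo",  # P = 144
  "C2'-endo",          # P = 162
  "C2'-endo/C3'-exo",  # P = 180
  "C3'-exo",           # P = 198
  "C4'-endo/C3'-exo",  # P = 216
  "C4'-endo",          # P = 234
  "C4'-endo/O4'-exo",  # P = 252
  "O4'-exo",           # P = 270
  "C1'-endo/O4'-exo",  # P = 288
  "C1'-endo",          # P = 306
  "C2'-exo/C1'-endo",  # P = 324
  "C2'-exo")           # P = 342

#' Pucker class from pseudorotation phase
#'
#' @param P Phase angle(s) in degrees.
#' @return Character vector of sector names from the 20 x 18-degree wheel
#'   (sectors half-open on the right).
#' @export
pucker_class <- function(P) {
  idx <- (floor(((P %% 360) + 9) / 18) %% 20) + 1
  .pucker_wheel[idx]
}

#' Pseudorotation phase and amplitude from ring torsions
#'
#' `tan(P) = ((nu4 + nu1) - (nu3 + nu0)) / (2 nu2 (sin 36 + sin 72))`,
#' quadrant-corrected so that `nu_max = nu2 / cos(P) >= 0`.  A ring that is
#' planar to within `tol` is reported with amplitude ~0 and class
#' `"planar/undefined"`.
#'
#' @param t A [ring_torsions()] object (or a 5-vector of degrees).
#' @param tol Planarity tolerance, degrees.
#' @return Object of class `pucker_state`: list with `P` (degrees, in
#'   `[0, 360)`), `nu_max` (degrees), `class`, and `rms_residual` (rms
#'   misfit, degrees, of the ideal cosine wave to the supplied torsions).
#' @export
pseudorotation_from_torsions <- function(t, tol = 1e-6) {
  if (!inherits(t, "ring_torsions")) t <- ring_torsions(t)
  s <- 2 * (sin(36 * pi / 180) + sin(72 * pi / 180))
  num <- (t[["nu4"]] + t[["nu1"]]) - (t[["nu3"]] + t[["nu0"]])
  den <- t[["nu2"]] * s
  if (abs(den) < tol && abs(num) < tol) {
    return(structure(list(P = NA_real_, nu_max = 0,
                          class = "planar/undefined", rms_residual = 0),
                     class = "pucker_state"))
  }
  P <- atan2(num, den) * 180 / pi
  P <- P %% 360
  if (P >= 360 - 1e-9) P <- 0
  # nu_max cos P = nu2 and nu_max sin P = num/s, hence:
  nu_max <- sqrt(t[["nu2"]]^2 + (num / s)^2)
  ideal <- torsions_from_pseudorotation(P, nu_max)
  rmsr <- sqrt(mean((as.numeric(t) - as.numeric(ideal))^2))
  structure(list(P = P, nu_max = nu_max, class = pucker_class(P),
                 rms_residual = rmsr),
            class = "pucker_state")
}

#' @export
print.pucker_state <- function(x, ...) {
  if (is.na(x$P)) {
    cat("Pucker: planar/undefined (amplitude ~ 0)\n")
  } else {
    cat(sprintf("Pucker: P = %.2f deg, nu_max = %.2f deg  [%s]\n",
                x$P, x$nu_max, x$class))
    if (x$rms_residual > 1e-6)
      cat(sprintf("  rms misfit to ideal wave: %.3g deg\n", x$rms_residual))
  }
  invisible(x)
}

#' Ideal ring torsions from pseudorotation parameters
#'
#' `nu_j = nu_max cos(P + 144 (j - 2))`, j = 0..4, so `nu2 = nu_max cos P`.
#'
#' @param P Phase, degrees.
#' @param nu_max Amplitude, degrees (>= 0).
#' @return A [ring_torsions()] object.
#' @export
torsions_from_pseudorotation <- function(P, nu_max) {
  stopifnot(length(P) == 1L, length(nu_max) == 1L, nu_max >= 0)
  j <- 0:4
  nu <- nu_max * cos((P + 144 * (j - 2)) * pi / 180)
  ring_torsions(nu)
}
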