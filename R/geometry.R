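# Dihedral angles and circular statistics over structure ensembles.

#' Dihedral angle from four points
#'
#' IUPAC sign convention (right-hand rule about the 2-3 bond; cis = 0,
#' trans = 180), range `(-180, 180]`.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (Angstrom).
#' @return Angle in degrees.
#' @export
dihedral_from_coords <- function(p1, p2, p3, p4) {
  pts <- list(p1, p2, p3, p4)
  if (!all(vapply(pts, function(p) is.numeric(p) && length(p) == 3L &&
                    all(is.finite(p)), logical(1))))
    stop("each point must be a finite numeric vector of length 3")
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("degenerate geometry: three consecutive points are collinear")
  b2u <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * b2u)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Circular mean and standard deviation of angles
#'
#' @param theta Angles in degrees.
#' @return Named vector `c(mean, sd)` in degrees; the mean is reported in
#'   `(-180, 180]`.  The sd is the circular standard deviation
#'   `sqrt(-2 log Rbar)` expressed in degrees.
#' @export
circular_stats <- function(theta) {
  theta <- theta[is.finite(theta)]
  if (!length(theta)) stop("no finite angles supplied")
  d <- pi / 180
  s <- mean(sin(theta * d)); c_ <- mean(cos(theta * d))
  m <- atan2(s, c_) / d
  if (m <= -180) m <- m + 360
  rbar <- min(sqrt(s^2 + c_^2), 1)
  sd <- if (rbar > 0) sqrt(-2 * log(rbar)) / d else Inf
  c(mean = m, sd = sd)
}

#' Per-model dihedral over a structure ensemble
#'
#' Measures one named dihedral (default the sugar H1'-C1'-C2'-H2' angle)
#' in every model of an ensemble and summarizes it with circular
#' statistics.  Models missing any of the four atoms are skipped with a
#' warning.
#'
#' @param ensemble A [read_pdb_models()] ensemble.
#' @param residue Residue selector `"chain:resnum"` or just the residue
#'   number (any chain).
#' @param atoms Character vector of the four atom names defining the
#'   dihedral (prime spellings are normalized).
#' @return List with `per_model` (numeric, degrees; `NA` for skipped
#'   models), `mean`, `sd` (circular, degrees), `n_used`, `n_skipped`.
#' @export
ensemble_dihedral <- function(ensemble, residue,
                              atoms = c("H1'", "C1'", "C2'", "H2'")) {
  stopifnot(inherits(ensemble, "model_ensemble"), length(atoms) == 4L)
  atoms <- normalize_primes(atoms)
  vals <- vapply(seq_along(ensemble$models), function(i) {
    coords <- lapply(atoms, function(a)
      lookup_atom(ensemble, i, residue, a, quiet = TRUE))
    if (any(vapply(coords, is.null, logical(1)))) return(NA_real_)
    dihedral_from_coords(coords[[1]], coords[[2]], coords[[3]], coords[[4]])
  }, numeric(1))
  n_skipped <- sum(is.na(vals))
  if (n_skipped > 0)
    warning(sprintf("%d model(s) skipped: missing atom(s) %s",
                    n_skipped, paste(atoms, collapse = "-")))
  if (all(is.na(vals)))
    stop("dihedral atoms missing in every model")
  cs <- circular_stats(vals)
  list(per_model = vals, mean = unname(cs["mean"]), sd = unname(cs["sd"]),
       n_used = sum(!is.na(vals)), n_skipped = n_skipped)
}

#' Heavy-atom r.m.s.d. of ensemble models against a reference model
#'
#' Each model is superposed onto the reference by the Kabsch algorithm
#' (optimal rotation after centering) over the atoms in common, and the
#' root-mean-square deviation is reported per model.
#'
#' @param ensemble A [read_pdb_models()] ensemble.
#' @param reference Index of the reference model (default 1).
#' @param heavy_only Drop hydrogens before superposition (default TRUE).
#' @return List with `per_model` (NA at the reference position), `mean`,
#'   `sd` over the non-reference models, and `n_atoms` used.
#' @export
ensemble_rmsd <- function(ensemble, reference = 1, heavy_only = TRUE) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  nm <- length(ensemble$models)
  if (reference < 1 || reference > nm) stop("reference model out of range")
  ref <- ensemble$models[[reference]]
  sel <- if (heavy_only) !(ref$element %in% c("H", "D"))
  else rep(TRUE, nrow(ref))
  key <- function(m) paste(m$chain, m$resno, m$atom_norm, sep = "|")
  ref_keys <- key(ref)[sel]
  vals <- rep(NA_real_, nm)
  n_atoms <- NA_integer_
  for (i in seq_len(nm)) {
    if (i == reference) next
    m <- ensemble$models[[i]]
    idx <- match(ref_keys, key(m))
    ok <- !is.na(idx)
    X <- as.matrix(ref[sel, c("x", "y", "z")])[ok, , drop = FALSE]
    Y <- as.matrix(m[idx[ok], c("x", "y", "z")])
    if (nrow(X) < 3L) stop("fewer than 3 atoms in common with the reference")
    n_atoms <- nrow(X)
    vals[i] <- .kabsch_rmsd(X, Y)
  }
  keep <- !is.na(vals)
  list(per_model = vals, mean = mean(vals[keep]), sd = stats::sd(vals[keep]),
       n_atoms = n_atoms)
}

# optimal-superposition rmsd between two N x 3 coordinate sets
.kabsch_rmsd <- function(X, Y) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  S <- svd(t(Yc) %*% Xc)        # C = U D V'; Yc R ~ Xc with R = U S V'
  d <- sign(det(S$u %*% t(S$v)))
  R <- S$u %*% diag(c(1, 1, d)) %*% t(S$v)
  Yr <- Yc %*% R
  sqrt(mean(rowSums((Xc - Yr)^2)))
}
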