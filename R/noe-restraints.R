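# NOE volume -> distance calibration (isolated spin-pair approximation),
# four-category restraint binning, bookkeeping and restraint-file writing.

# category -> (lower, upper) bounds in Angstrom
.category_bounds <- data.frame(
  category = c("strong", "medium", "weak", "very weak"),
  lower = c(1.8, 1.8, 3.0, 4.0),
  upper = c(3.0, 4.5, 6.0, 7.0),
  stringsAsFactors = FALSE)

#' NOE category bounds table
#'
#' Distance bounds for the four restraint categories: strong (1.8-3.0 A),
#' medium (1.8-4.5 A), weak (3.0-6.0 A), very weak (4.0-7.0 A).
#'
#' @return Data frame with columns `category`, `lower`, `upper`.
#' @export
noe_category_bounds <- function() .category_bounds

#' Build an NOE peak table
#'
#' @param res_i,res_j Residue indices (>= 1).
#' @param atom_i,atom_j Atom names.
#' @param volume Integrated peak volumes (> 0, arbitrary units).
#' @param mixing_time_s Mixing time of the spectrum (s), stored as an
#'   attribute.
#' @return Data frame of class `noe_peaks`.
#' @export
noe_peaks <- function(res_i, atom_i, res_j, atom_j, volume,
                      mixing_time_s = 0.25) {
  n <- length(volume)
  stopifnot(length(res_i) == n, length(res_j) == n,
            length(atom_i) == n, length(atom_j) == n)
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("volumes must be finite and > 0")
  if (any(res_i < 1) || any(res_j < 1))
    stop("residue indices must be >= 1")
  df <- data.frame(res_i = as.integer(res_i),
                   atom_i = normalize_atom_name(atom_i),
                   res_j = as.integer(res_j),
                   atom_j = normalize_atom_name(atom_j),
                   volume = as.numeric(volume),
                   stringsAsFactors = FALSE)
  attr(df, "mixing_time_s") <- mixing_time_s
  class(df) <- c("noe_peaks", "data.frame")
  df
}

#' Read an NOE peak table from TSV
#'
#' Columns: `res_i`, `atom_i`, `res_j`, `atom_j`, `volume`.
#' @param path File path.
#' @return A [noe_peaks()] table.
#' @export
read_noe_peaks <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("res_i", "atom_i", "res_j", "atom_j", "volume")
  if (!all(need %in% names(df)))
    stop(sprintf("missing required columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  noe_peaks(df$res_i, df$atom_i, df$res_j, df$atom_j, df$volume)
}

#' Calibrate NOE volumes to distances (ISPA)
#'
#' Isolated spin-pair approximation against a reference peak of known
#' separation: `r_i = r_ref * (V_ref / V_i)^(1/6)`.  The default reference
#' is the covalently fixed pyrimidine H5-H6 pair at 2.45 A.
#'
#' @param peaks A [noe_peaks()] table containing the reference pair.
#' @param reference List with `res`, `atom_i`, `atom_j` identifying the
#'   reference peak (atom order ignored) and `distance` (A).
#' @return The table with a calibrated `r` column (class `noe_peaks`).
#' @export
calibrate_distances <- function(peaks,
                                reference = list(res = 1, atom_i = "H5",
                                                 atom_j = "H6",
                                                 distance = 2.45)) {
  stopifnot(inherits(peaks, "noe_peaks"))
  ai <- normalize_atom_name(reference$atom_i)
  aj <- normalize_atom_name(reference$atom_j)
  hit <- which(
    peaks$res_i == reference$res & peaks$res_j == reference$res &
      ((peaks$atom_i == ai & peaks$atom_j == aj) |
         (peaks$atom_i == aj & peaks$atom_j == ai)))
  if (!length(hit))
    stop(sprintf("reference pair %s-%s in residue %s not found in the table",
                 reference$atom_i, reference$atom_j,
                 as.character(reference$res)))
  v_ref <- peaks$volume[hit[1]]
  if (v_ref <= 0) stop("reference volume must be > 0")
  peaks$r <- reference$distance * (v_ref / peaks$volume)^(1 / 6)
  peaks
}

#' Assign calibrated peaks to restraint categories
#'
#' Categories by calibrated distance, half-open on the right:
#' `r < 3.0` strong; `3.0 <= r < 4.5` medium; `4.5 <= r < 6.0` weak;
#' `r >= 6.0` very weak.  Each restraint carries the category's fixed
#' bounds and a range class from the residue separation (`|i-j|`: 0 intra,
#' 1 sequential, >= 2 long-range).
#'
#' @param peaks A calibrated [noe_peaks()] table (with `r`).
#' @param pseudo_atom_correction Add 1.0 A to the upper bound of restraints
#'   involving methyl/amine pseudo-atoms (default off).
#' @return Data frame of class `noe_restraints` with columns `res_i`,
#'   `atom_i`, `res_j`, `atom_j`, `r`, `category`, `lower`, `upper`,
#'   `range_class`.
#' @export
assign_categories <- function(peaks, pseudo_atom_correction = FALSE) {
  stopifnot(inherits(peaks, "noe_peaks"))
  if (is.null(peaks$r))
    stop("no calibrated distances; run calibrate_distances() first")
  if (any(peaks$r <= 0)) stop("calibrated distances must be > 0")
  cat_idx <- findInterval(peaks$r, c(3.0, 4.5, 6.0)) + 1L
  cats <- .category_bounds$category[cat_idx]
  out <- data.frame(
    res_i = peaks$res_i, atom_i = peaks$atom_i,
    res_j = peaks$res_j, atom_j = peaks$atom_j,
    r = peaks$r,
    category = cats,
    lower = .category_bounds$lower[cat_idx],
    upper = .category_bounds$upper[cat_idx],
    stringsAsFactors = FALSE)
  if (pseudo_atom_correction) {
    pseudo <- grepl("^(M|Q)", out$atom_i) | grepl("^(M|Q)", out$atom_j) |
      out$atom_i %in% c("H41", "H42", "H21", "H22", "H61", "H62") |
      out$atom_j %in% c("H41", "H42", "H21", "H22", "H61", "H62")
    out$upper[pseudo] <- out$upper[pseudo] + 1.0
  }
  sep <- abs(out$res_i - out$res_j)
  out$range_class <- ifelse(sep == 0, "intra",
                            ifelse(sep == 1, "sequential", "long-range"))
  class(out) <- c("noe_restraints", "data.frame")
  out
}

#' Tally restraints in the style of an NMR statistics table
#'
#' @param restraints A [assign_categories()] table.
#' @param n_residues Number of residues in the duplex, used for the
#'   per-residue ratio (reported to two decimals, as conventionally
#'   printed).
#' @param mismatch_residues Optional integer vector of residue indices
#'   belonging to the mismatch/metallo base pairs; restraints with either
#'   atom in this set are counted separately.
#' @return List with `total`, `intra`, `sequential`, `long_range`,
#'   `mismatch`, `per_residue` (rounded to 2 decimals) and
#'   `per_residue_exact`.
#' @export
classify_and_count <- function(restraints, n_residues,
                               mismatch_residues = NULL) {
  if (!is.null(restraints) && nrow(restraints) == 0)
    return(list(total = 0L, intra = 0L, sequential = 0L, long_range = 0L,
                mismatch = 0L, per_residue = 0, per_residue_exact = 0))
  stopifnot(inherits(restraints, "noe_restraints"))
  if (missing(n_residues) || n_residues < 1)
    stop("supply the duplex length 'n_residues'")
  total <- nrow(restraints)
  tab <- table(factor(restraints$range_class,
                      levels = c("intra", "sequential", "long-range")))
  mism <- if (is.null(mismatch_residues)) 0L else
    sum(restraints$res_i %in% mismatch_residues |
          restraints$res_j %in% mismatch_residues)
  exact <- total / n_residues
  list(total = total,
       intra = unname(tab[["intra"]]),
       sequential = unname(tab[["sequential"]]),
       long_range = unname(tab[["long-range"]]),
       mismatch = mism,
       per_residue = round(exact, 2),
       per_residue_exact = exact)
}

#' Write restraints to file
#'
#' The `xplor` dialect emits one `assign` statement per restraint using the
#' category bounds: centre `d = lower + (upper - lower)/2`, minus range
#' `d - lower`, plus range `upper - d`, each printed with one decimal.
#' The `tsv` dialect mirrors all restraint fields and can be read back
#' with [read_restraints_tsv()].
#'
#' @param restraints A non-empty [assign_categories()] table.
#' @param path Output path.
#' @param dialect `"tsv"` or `"xplor"`.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(restraints, path, dialect = c("tsv", "xplor")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(restraints, "noe_restraints"))
  if (nrow(restraints) == 0) stop("no restraints to write")
  if (dialect == "tsv") {
    utils::write.table(as.data.frame(restraints), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    d <- restraints$lower + (restraints$upper - restraints$lower) / 2
    lines <- sprintf(
      "assign (resid %d and name %s) (resid %d and name %s) %.1f %.1f %.1f",
      restraints$res_i, restraints$atom_i,
      restraints$res_j, restraints$atom_j,
      d, d - restraints$lower, restraints$upper - d)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read back a TSV restraint file
#'
#' @param path File written by [write_restraints()] with `dialect = "tsv"`.
#' @return A `noe_restraints` data frame.
#' @export
read_restraints_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("res_i", "atom_i", "res_j", "atom_j", "r", "category",
            "lower", "upper", "range_class")
  if (!all(need %in% names(df)))
    stop(sprintf("missing required columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  class(df) <- c("noe_restraints", "data.frame")
  df
}
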