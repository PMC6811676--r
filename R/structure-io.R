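# Multi-model PDB reading into a light ensemble representation.
#
# Record parsing is delegated to bio3d::read.pdb; this layer handles MODEL
# bookkeeping, altloc resolution, atom-name normalization and lookup.

#' Normalize an atom name
#'
#' Folds typographic primes and the PDB `*` prime dialect to ASCII `'`,
#' and rewrites version-2 hydrogen names with a leading digit
#' (`"1H2'" -> "H2'"`, `"2H2'" -> "H2''"`).  Idempotent.
#'
#' @param x Character vector of atom names.
#' @return Normalized names.
#' @export
normalize_atom_name <- function(x) {
  x <- trimws(normalize_primes(x))
  lead1 <- grepl("^1H", x)
  lead2 <- grepl("^2H", x)
  x[lead1] <- sub("^1", "", x[lead1])
  x[lead2] <- paste0(sub("^2", "", x[lead2]), "'")
  x
}

#' Construct a model ensemble
#'
#' Usually produced by [read_pdb_models()]; exposed so synthetic ensembles
#' can be built in code.
#'
#' @param models List of per-model data.frames with columns `atom`,
#'   `atom_norm`, `resno`, `chain`, `resid`, `x`, `y`, `z`, `element`,
#'   `het`.
#' @param id Entry identifier string.
#' @return Object of class `model_ensemble`.
#' @export
model_ensemble <- function(models, id = "") {
  if (!length(models)) stop("an ensemble needs at least one model")
  need <- c("atom", "atom_norm", "resno", "chain", "resid",
            "x", "y", "z", "element", "het")
  for (m in models) {
    if (!is.data.frame(m) || !all(need %in% names(m)))
      stop("each model must be a data.frame with columns: ",
           paste(need, collapse = ", "))
    if (any(!is.finite(as.matrix(m[, c("x", "y", "z")]))))
      stop("coordinates must be finite")
  }
  structure(list(models = models, id = id, n_models = length(models)),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf("Model ensemble%s: %d model(s), %d atoms in model 1\n",
              if (nzchar(x$id)) paste0(" [", x$id, "]") else "",
              x$n_models, nrow(x$models[[1]])))
  invisible(x)
}

#' Read a (multi-model) PDB file into an ensemble
#'
#' One ensemble entry per MODEL block; files without MODEL records yield an
#' ensemble of one.  HETATM records (e.g. coordinated metal ions) are
#' retained.  Alternate locations are resolved by highest occupancy, ties
#' broken by altloc label order.  When models do not share the same atom
#' set, the intersection is used with a warning.  Gzip-compressed files are
#' read transparently.
#'
#' @param path Path to a PDB (or PDB.gz) file.
#' @return A [model_ensemble()].
#' @export
read_pdb_models <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  lines <- readLines(con, warn = FALSE)
  close(con)
  .check_atom_records(lines)

  starts <- grep("^MODEL", lines)
  if (!length(starts)) {
    chunks <- list(lines)
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(starts)) ends <- c(ends, length(lines))
    chunks <- Map(function(s, e) lines[(s + 1):(e - 1)], starts, ends)
  }
  models <- lapply(chunks, .parse_model_chunk)
  models <- Filter(function(m) nrow(m) > 0, models)
  if (!length(models)) stop(sprintf("no coordinate records in %s", path))

  # harmonize atom sets across models
  key <- function(m) paste(m$chain, m$resno, m$atom_norm, sep = "|")
  keys <- lapply(models, key)
  common <- Reduce(intersect, keys)
  if (any(vapply(keys, length, integer(1)) != length(common))) {
    warning(sprintf(
      "models differ in atom content; using the %d atoms in common",
      length(common)))
    models <- Map(function(m, k) m[match(common, k), , drop = FALSE],
                  models, keys)
  }
  id <- sub("^HEADER\\s+.*?(\\S+)\\s*$", "\\1",
            grep("^HEADER", lines, value = TRUE)[1])
  if (is.na(id)) id <- basename(path)
  model_ensemble(models, id = id)
}

# fail fast, with a line number, on truncated/garbled coordinate records
.check_atom_records <- function(lines) {
  rec <- grepl("^(ATOM|HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    bad <- nchar(ln) < 54 ||
      anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                          substr(ln, 39, 46),
                                          substr(ln, 47, 54)))))
    if (bad)
      stop(sprintf("malformed ATOM/HETATM record at line %d: '%s'",
                   i, substr(ln, 1, 30)))
  }
  invisible(TRUE)
}

.parse_model_chunk <- function(lines) {
  keep <- grepl("^(ATOM|HETATM)", lines)
  lines <- lines[keep]
  if (!length(lines))
    return(data.frame(atom = character(0), atom_norm = character(0),
                      resno = integer(0), chain = character(0),
                      resid = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), element = character(0),
                      het = logical(0)))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(c(lines, "END"), tmp)
  pdb <- bio3d::read.pdb(tmp, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  df <- data.frame(
    atom = at$elety,
    atom_norm = normalize_atom_name(at$elety),
    resno = at$resno,
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    resid = at$resid,
    x = at$x, y = at$y, z = at$z,
    element = .element_of(at),
    het = at$type == "HETATM",
    alt = ifelse(is.na(at$alt), "", at$alt),
    o = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE)
  .resolve_altloc(df)
}

.element_of <- function(at) {
  el <- if ("elesy" %in% names(at)) trimws(at$elesy) else rep("", nrow(at))
  el[is.na(el)] <- ""
  guess <- toupper(substr(gsub("[0-9']", "",
                               normalize_atom_name(at$elety)), 1, 1))
  el[el == ""] <- guess[el == ""]
  # title-case so two-letter elements read naturally (HG -> Hg)
  ifelse(nchar(el) > 1,
         paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2))),
         toupper(el))
}

# highest occupancy wins; ties broken by altloc label order
.resolve_altloc <- function(df) {
  if (all(df$alt == "")) return(df[, setdiff(names(df), c("alt", "o"))])
  k <- paste(df$chain, df$resno, df$atom_norm, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(df)), k), function(ix) {
    if (length(ix) == 1L) return(ix)
    ix <- ix[order(-df$o[ix], df$alt[ix])]
    ix[1]
  }), use.names = FALSE)
  df <- df[sort(keep), , drop = FALSE]
  rownames(df) <- NULL
  df[, setdiff(names(df), c("alt", "o"))]
}

# parse "chain:resnum" or a bare residue number
.parse_selector <- function(residue) {
  if (is.numeric(residue)) return(list(chain = NULL, resno = residue))
  if (grepl(":", residue)) {
    parts <- strsplit(residue, ":", fixed = TRUE)[[1]]
    list(chain = parts[1], resno = as.integer(parts[2]))
  } else list(chain = NULL, resno = as.integer(residue))
}

#' Look up an atom's coordinates
#'
#' @param ensemble A [model_ensemble()].
#' @param model Model index.
#' @param residue Residue selector `"chain:resnum"` or residue number.
#' @param atom Atom name (normalized before matching).
#' @param quiet Return `NULL` instead of erroring when absent.
#' @return Numeric xyz vector, or `NULL` when `quiet` and absent.
#' @export
lookup_atom <- function(ensemble, model, residue, atom, quiet = FALSE) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  if (model < 1 || model > ensemble$n_models) stop("model index out of range")
  m <- ensemble$models[[model]]
  sel <- .parse_selector(residue)
  hit <- m$resno == sel$resno & m$atom_norm == normalize_atom_name(atom)
  if (!is.null(sel$chain)) hit <- hit & m$chain == sel$chain
  i <- which(hit)
  if (!length(i)) {
    if (quiet) return(NULL)
    stop(sprintf("atom '%s' not found in residue %s (model %d)",
                 atom, as.character(residue), model))
  }
  as.numeric(m[i[1], c("x", "y", "z")])
}

.ring_atoms <- c("O4'", "C1'", "C2'", "C3'", "C4'")

#' Extract the five endocyclic sugar torsions from a model
#'
#' Torsions are returned in the standard order `nu0 (C4'-O4'-C1'-C2')`,
#' `nu1 (O4'-C1'-C2'-C3')`, `nu2 (C1'-C2'-C3'-C4')`,
#' `nu3 (C2'-C3'-C4'-O4')`, `nu4 (C3'-C4'-O4'-C1')`.
#'
#' @param ensemble A [model_ensemble()].
#' @param residue Residue selector (see [lookup_atom()]).
#' @param model Model index (default 1).
#' @return A [ring_torsions()] object.
#' @export
extract_ring_torsions <- function(ensemble, residue, model = 1) {
  coords <- lapply(.ring_atoms, function(a) {
    p <- lookup_atom(ensemble, model, residue, a, quiet = TRUE)
    if (is.null(p))
      stop(sprintf("ring atom %s missing in residue %s", a,
                   as.character(residue)))
    p
  })
  names(coords) <- .ring_atoms
  tor <- function(a, b, c_, d)
    dihedral_from_coords(coords[[a]], coords[[b]], coords[[c_]], coords[[d]])
  ring_torsions(c(
    tor("C4'", "O4'", "C1'", "C2'"),
    tor("O4'", "C1'", "C2'", "C3'"),
    tor("C1'", "C2'", "C3'", "C4'"),
    tor("C2'", "C3'", "C4'", "O4'"),
    tor("C3'", "C4'", "O4'", "C1'")))
}

#' Write an ensemble (or model list) as a multi-model PDB file
#'
#' Minimal fixed-width writer used for synthetic fixtures; emits
#' MODEL/ENDMDL blocks, ATOM/HETATM records and END.
#'
#' @param ensemble A [model_ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_models <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  out <- character(0)
  multi <- ensemble$n_models > 1
  for (i in seq_len(ensemble$n_models)) {
    m <- ensemble$models[[i]]
    if (multi) out <- c(out, sprintf("MODEL     %4d", i))
    for (j in seq_len(nrow(m))) {
      nm <- m$atom[j]
      nmf <- if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
      out <- c(out, sprintf(
        "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        if (m$het[j]) "HETATM" else "ATOM", j, nmf, m$resid[j], m$chain[j],
        m$resno[j], m$x[j], m$y[j], m$z[j], 1, 0,
        toupper(m$element[j])))
    }
    if (multi) out <- c(out, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Build an idealized puckered furanose ring
#'
#' Places the five ring atoms (`O4'`, `C1'`..`C4'`) on a pentagon with an
#' out-of-plane cosine displacement, then calibrates the displacement
#' phase and scale so the measured pseudorotation matches the requested
#' `(P, nu_max)`.  Intended for synthetic fixtures and round-trip tests;
#' exocyclic atoms are not built.
#'
#' @param P Target pseudorotation phase, degrees.
#' @param nu_max Target amplitude, degrees (0 gives a planar ring).
#' @param resno,chain,resid Residue bookkeeping for the returned model.
#' @return A one-model data.frame suitable for [model_ensemble()].
#' @export
build_sugar_ring <- function(P, nu_max, resno = 1, chain = "A",
                             resid = "DC") {
  stopifnot(nu_max >= 0)
  ring_df <- function(delta, q) {
    k <- 0:4
    r <- 1.45 / (2 * sin(pi / 5))
    ang <- 2 * pi * k / 5
    z <- q * cos(4 * pi * k / 5 + delta)
    data.frame(
      atom = .ring_atoms, atom_norm = .ring_atoms,
      resno = resno, chain = chain, resid = resid,
      x = r * cos(ang), y = r * sin(ang), z = z,
      element = c("O", "C", "C", "C", "C"), het = FALSE,
      stringsAsFactors = FALSE)
  }
  measure <- function(delta, q) {
    ens <- model_ensemble(list(ring_df(delta, q)))
    pseudorotation_from_torsions(extract_ring_torsions(ens, resno))
  }
  if (nu_max == 0) return(ring_df(0, 0))
  # Newton iteration on the displacement phase (radians) and scale: the
  # measured phase is monotone in delta and the amplitude ~linear in q.
  delta <- 0; q <- 0.4; h <- 0.01
  for (iter in 1:12) {
    st <- measure(delta, q)
    if (is.na(st$P) || st$nu_max < 1e-6) { q <- q * 2; next }
    q <- q * nu_max / st$nu_max
    st <- measure(delta, q)
    dP <- ((P - st$P + 180) %% 360) - 180          # degrees, wrapped
    if (abs(dP) < 1e-4 && abs(st$nu_max - nu_max) < 1e-4) break
    st2 <- measure(delta + h, q)
    slope <- (((st2$P - st$P + 180) %% 360) - 180) / h  # deg per rad
    if (abs(slope) < 1e-6) slope <- 57.3
    delta <- delta + dP / slope
  }
  ring_df(delta, q)
}
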