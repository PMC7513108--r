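# Structure input/output and internal coordinates.

#' Construct a structure model
#'
#' A `structure_model` holds one protein conformation: a table of heavy
#' atoms with coordinates in Angstrom, per-residue bookkeeping and the
#' one-letter amino-acid sequence. Residues missing any of the N, CA, C
#' backbone atoms are flagged incomplete; torsions involving them are
#' never emitted.
#'
#' @param atoms data.frame with columns `name` (PDB atom name), `element`,
#'   `resno` (1-based residue index), `resid` (3-letter residue type),
#'   `chain`, `x`, `y`, `z` (Angstrom). Optional `b` (B-factor).
#' @param model_id integer model identifier (MODEL number for multi-model
#'   files).
#' @return An object of class `structure_model` with fields `atoms`,
#'   `sequence`, `model_id`, `residues` (per-residue table with an
#'   `incomplete` flag).
#' @export
structure_model <- function(atoms, model_id = 1L) {
  req <- c("name", "element", "resno", "resid", "chain", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("empty structure: no atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  if (is.null(atoms$b)) atoms$b <- 0
  atoms$name <- trimws(atoms$name)
  atoms$element <- trimws(atoms$element)

  # residue bookkeeping; indices must be strictly increasing within a chain
  key <- !duplicated(paste(atoms$chain, atoms$resno))
  residues <- data.frame(
    chain = atoms$chain[key], resno = atoms$resno[key],
    resid = atoms$resid[key], stringsAsFactors = FALSE
  )
  for (ch in unique(residues$chain)) {
    rn <- residues$resno[residues$chain == ch]
    if (any(diff(rn) <= 0)) {
      stop("residue indices not strictly increasing in chain ", ch)
    }
  }
  residues$incomplete <- vapply(seq_len(nrow(residues)), function(i) {
    sel <- atoms$chain == residues$chain[i] & atoms$resno == residues$resno[i]
    !all(c("N", "CA", "C") %in% atoms$name[sel])
  }, logical(1))

  seq1 <- paste(bio3d::aa321(residues$resid), collapse = "")
  structure(
    list(atoms = atoms, residues = residues, sequence = seq1,
         model_id = as.integer(model_id)),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$residues), "residues,",
      nrow(x$atoms), "atoms, model", x$model_id, "\n")
  cat("  chains:", paste(unique(x$residues$chain), collapse = " "), "\n")
  cat("  sequence:", x$sequence, "\n")
  if (any(x$residues$incomplete)) {
    cat("  incomplete residues:",
        paste(x$residues$resno[x$residues$incomplete], collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of residues in a structure model
#' @param x a `structure_model`
#' @return integer residue count
#' @export
n_residues <- function(x) nrow(x$residues)

# coordinates of one named atom of a residue, or NULL if absent
.atom_xyz <- function(model, chain, resno, name) {
  a <- model$atoms
  sel <- which(a$chain == chain & a$resno == resno & a$name == name)
  if (length(sel) == 0) return(NULL)
  as.numeric(a[sel[1], c("x", "y", "z")])
}

# quick pre-scan of ATOM/HETATM records so malformed input fails with a
# line-numbered message rather than an opaque parser error
.validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(idx) == 0) stop("empty structure: no ATOM records in ", path)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop("malformed PDB record at line ", i, " of ", path,
           ": fewer than 54 columns")
    }
    coords <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (any(is.na(coords))) {
      stop("malformed PDB record at line ", i, " of ", path,
           ": non-numeric coordinates")
    }
  }
  invisible(TRUE)
}

#' Read a protein structure (or ensemble) from a PDB file
#'
#' Parses ATOM records (HETATM and hydrogens are ignored). Alternate
#' locations are resolved to the highest-occupancy record, ties to the
#' first. Multi-model files yield one model per MODEL block when
#' `policy = "all"`.
#'
#' @param path path to a PDB file.
#' @param policy `"first"` returns a single `structure_model`;
#'   `"all"` returns a `structure_ensemble` (list of models).
#' @return A `structure_model`, or a `structure_ensemble` when
#'   `policy = "all"`.
#' @export
read_pdb <- function(path, policy = c("first", "all")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("file not found: ", path)
  .validate_pdb_lines(path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB ", path, ": ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  keep <- at$type == "ATOM" & !(toupper(at$elesy) %in% "H")
  if (!any(keep)) stop("empty structure: no non-hydrogen ATOM records")

  # resolve altlocs: highest occupancy wins, ties to first record
  occ <- at$o
  occ[is.na(occ)] <- 1
  akey <- paste(at$chain, at$resno, at$elety)
  best <- rep(FALSE, nrow(at))
  for (k in unique(akey[keep])) {
    idx <- which(keep & akey == k)
    best[idx[which.max(occ[idx])]] <- TRUE
  }

  nmodels <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1
  build_one <- function(m) {
    xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[m, ] else as.numeric(pdb$xyz)
    xm <- matrix(xyz, ncol = 3, byrow = TRUE)
    elem <- toupper(trimws(at$elesy))
    elem[is.na(elem) | elem == ""] <-
      substr(trimws(at$elety[is.na(elem) | elem == ""]), 1, 1)
    atoms <- data.frame(
      name = trimws(at$elety), element = elem,
      resno = at$resno, resid = at$resid, chain = at$chain,
      x = xm[, 1], y = xm[, 2], z = xm[, 3],
      b = at$b, stringsAsFactors = FALSE
    )[best, , drop = FALSE]
    rownames(atoms) <- NULL
    structure_model(atoms, model_id = m)
  }

  if (policy == "first") return(build_one(1))
  models <- lapply(seq_len(nmodels), build_one)
  structure(models, class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat("structure_ensemble:", length(x), "models of",
      n_residues(x[[1]]), "residues\n")
  invisible(x)
}

#' Write a structure model (or ensemble) to a PDB file
#'
#' Per-residue scalars (for example partial entropies or their
#' differences) can be placed in the B-factor column for coloring in
#' molecular viewers.
#'
#' @param x a `structure_model` or `structure_ensemble`.
#' @param path output file.
#' @param bfactor optional numeric vector of per-residue values, length
#'   equal to the residue count; written to the B-factor column of every
#'   atom of the residue.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path, bfactor = NULL) {
  models <- if (inherits(x, "structure_ensemble")) x else list(x)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    a <- m$atoms
    bvals <- a$b
    if (!is.null(bfactor)) {
      if (length(bfactor) != nrow(m$residues)) {
        stop("bfactor length ", length(bfactor), " != residue count ",
             nrow(m$residues))
      }
      rkey <- paste(m$residues$chain, m$residues$resno)
      bvals <- bfactor[match(paste(a$chain, a$resno), rkey)]
    }
    if (multi) writeLines(sprintf("MODEL     %4d", mi), con)
    for (i in seq_len(nrow(a))) {
      nm <- a$name[i]
      # PDB atom-name alignment: element-right names start in column 14
      nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      writeLines(sprintf(
        "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        i, nm_fmt, a$resid[i], a$chain[i], a$resno[i],
        a$x[i], a$y[i], a$z[i], 1.0, bvals[i], a$element[i]
      ), con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: looking down the p2-p3 bond, a clockwise
#' rotation of the far bond is positive. The planar anti arrangement
#' gives +pi, the syn arrangement 0; values lie in (-pi, pi].
#'
#' @param p1,p2,p3,p4 numeric xyz vectors (Angstrom).
#' @return angle in radians.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  if (sqrt(sum(b1^2)) < 1e-10 || sqrt(sum(b2^2)) < 1e-10 ||
      sqrt(sum(b3^2)) < 1e-10) {
    stop("undefined dihedral: coincident consecutive points")
  }
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    stop("undefined dihedral: collinear consecutive points")
  }
  m <- cross(n1, n2)
  atan2(sum(m * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

# torsion atom quadruple for one labelled torsion, or NULL if any atom
# is missing (chain ends, incomplete residues, absent side-chain atoms)
.torsion_atoms <- function(model, chain, resno, torsion) {
  res <- model$residues
  here <- which(res$chain == chain & res$resno == resno)
  if (length(here) == 0 || res$incomplete[here]) return(NULL)
  prev <- which(res$chain == chain & res$resno == resno - 1)
  nxt <- which(res$chain == chain & res$resno == resno + 1)
  get <- function(rn, nm) .atom_xyz(model, chain, rn, nm)
  if (torsion == "phi") {
    if (length(prev) == 0 || res$incomplete[prev]) return(NULL)
    pts <- list(get(resno - 1, "C"), get(resno, "N"),
                get(resno, "CA"), get(resno, "C"))
  } else if (torsion == "psi") {
    if (length(nxt) == 0 || res$incomplete[nxt]) return(NULL)
    pts <- list(get(resno, "N"), get(resno, "CA"),
                get(resno, "C"), get(resno + 1, "N"))
  } else {
    k <- as.integer(sub("chi", "", torsion))
    defs <- .CHI_ATOMS[[res$resid[here]]]
    if (is.null(defs) || k > length(defs)) return(NULL)
    pts <- lapply(defs[[k]], function(nm) get(resno, nm))
  }
  if (any(vapply(pts, is.null, logical(1)))) return(NULL)
  pts
}

# all defined torsion labels of one model: data.frame(chain, resno, torsion)
.torsion_labels <- function(model, quiet = FALSE) {
  res <- model$residues
  out <- list()
  for (i in seq_len(nrow(res))) {
    ch <- res$chain[i]; rn <- res$resno[i]
    cand <- c("phi", "psi", paste0("chi", 1:4))
    for (tor in cand) {
      if (startsWith(tor, "chi")) {
        defs <- .CHI_ATOMS[[res$resid[i]]]
        k <- as.integer(sub("chi", "", tor))
        if (is.null(defs) || k > length(defs)) next
        if (is.null(.torsion_atoms(model, ch, rn, tor))) {
          if (!quiet && !res$incomplete[i]) {
            warning("residue ", rn, " (", res$resid[i], "): missing atoms for ",
                    tor, "; torsion omitted", call. = FALSE)
          }
          next
        }
      } else if (is.null(.torsion_atoms(model, ch, rn, tor))) next
      out[[length(out) + 1]] <- data.frame(
        chain = ch, resno = rn, torsion = tor, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(chain = character(), resno = integer(),
                      torsion = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Construct a torsion ensemble
#'
#' @param samples numeric matrix, frames x torsions, radians; column names
#'   are torsion labels of the form `"phi_3"`, `"chi2_7"`.
#' @param labels data.frame with columns `resno` and `torsion`; derived
#'   from `colnames(samples)` when omitted.
#' @param sequence one-letter amino-acid sequence.
#' @return An object of class `torsion_ensemble`.
#' @export
torsion_ensemble <- function(samples, labels = NULL, sequence = NULL) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 1) stop("torsion ensemble needs at least one frame")
  if (is.null(labels) && ncol(samples) == 0) {
    labels <- data.frame(resno = integer(), torsion = character(),
                         stringsAsFactors = FALSE)
  } else if (is.null(labels)) {
    if (is.null(colnames(samples))) stop("samples need column labels")
    parts <- strsplit(colnames(samples), "_", fixed = TRUE)
    labels <- data.frame(
      resno = vapply(parts, function(p) as.integer(p[2]), integer(1)),
      torsion = vapply(parts, `[`, character(1), 1),
      stringsAsFactors = FALSE
    )
  }
  lab <- paste0(labels$torsion, "_", labels$resno)
  if (anyDuplicated(lab)) stop("duplicate torsion labels")
  if (ncol(samples) > 0) colnames(samples) <- lab
  samples[] <- .wrap_angle(samples)
  if (is.null(sequence)) sequence <- strrep("A", max(labels$resno))
  structure(
    list(samples = samples, labels = labels, sequence = sequence),
    class = "torsion_ensemble"
  )
}

#' @export
print.torsion_ensemble <- function(x, ...) {
  cat("torsion_ensemble:", nrow(x$samples), "frames x",
      ncol(x$samples), "torsions,", nchar(x$sequence), "residues\n")
  invisible(x)
}

#' Compute backbone and side-chain torsions of a structure ensemble
#'
#' Emits phi/psi (phi absent for the first residue of a chain, psi for the
#' last) and chi1..chi4 up to the side-chain length of each residue type;
#' omega is treated as rigid and never emitted. All models must share
#' sequence and atom naming. Values are wrapped into \[-pi, pi).
#'
#' @param x a `structure_model`, `structure_ensemble`, or plain list of
#'   models.
#' @return A `torsion_ensemble` with one frame per model.
#' @export
compute_torsions <- function(x) {
  models <- if (inherits(x, "structure_model")) list(x) else x
  seqs <- vapply(models, function(m) m$sequence, character(1))
  if (length(unique(seqs)) != 1) {
    stop("models differ in sequence: model 1 vs model ",
         which(seqs != seqs[1])[1])
  }
  labels <- .torsion_labels(models[[1]])
  lab_str <- paste0(labels$torsion, "_", labels$resno)
  if (length(models) > 1) {
    for (m in seq_along(models)[-1]) {
      lm <- .torsion_labels(models[[m]], quiet = TRUE)
      lm_str <- paste0(lm$torsion, "_", lm$resno)
      if (!identical(lm_str, lab_str)) {
        bad <- c(setdiff(lab_str, lm_str), setdiff(lm_str, lab_str))
        stop("model ", m, " torsion labels mismatch; first difference: ",
             bad[1])
      }
    }
  }
  samples <- matrix(NA_real_, nrow = length(models), ncol = nrow(labels))
  if (nrow(labels) > 0) colnames(samples) <- lab_str
  for (m in seq_along(models)) {
    for (j in seq_len(nrow(labels))) {
      pts <- .torsion_atoms(models[[m]], labels$chain[j], labels$resno[j],
                            labels$torsion[j])
      samples[m, j] <- dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    }
  }
  torsion_ensemble(samples, labels, sequence = seqs[1])
}
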