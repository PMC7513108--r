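# Configurational entropy from torsion-angle ensembles: histogram
# marginal entropies minus mutual information of covalently adjacent
# torsion pairs, aggregated into per-residue partial entropies.

#' Covalently adjacent torsion pairs of an ensemble
#'
#' Within residue i the pairs are (phi,psi), (phi,chi1), (psi,chi1) and
#' (chik,chik+1); across the peptide bond (psi_i, phi_i+1) links adjacent
#' residues. Each pair is charged ("owned") to exactly one residue so the
#' per-residue partial entropies sum to a well-defined total:
#' intra-residue pairs to residue i, the cross-residue pair to residue
#' i+1. This adjacency convention (all covalent neighbours, not a maximum
#' information spanning tree) is a documented stand-in; see the methods
#' vignette.
#'
#' @param ensemble a `torsion_ensemble`.
#' @return An object of class `torsion_adjacency`: data.frame with
#'   columns `a`, `b` (torsion labels) and `owner` (residue index).
#' @export
build_adjacency <- function(ensemble) {
  lab <- ensemble$labels
  lab$full <- paste0(lab$torsion, "_", lab$resno)
  has <- function(rn, tor) any(lab$resno == rn & lab$torsion == tor)
  nm <- function(rn, tor) paste0(tor, "_", rn)
  pairs <- list()
  add <- function(a, b, owner) {
    pairs[[length(pairs) + 1]] <<- data.frame(
      a = a, b = b, owner = owner, stringsAsFactors = FALSE
    )
  }
  for (rn in sort(unique(lab$resno))) {
    if (has(rn, "phi") && has(rn, "psi")) add(nm(rn, "phi"), nm(rn, "psi"), rn)
    if (has(rn, "phi") && has(rn, "chi1")) add(nm(rn, "phi"), nm(rn, "chi1"), rn)
    if (has(rn, "psi") && has(rn, "chi1")) add(nm(rn, "psi"), nm(rn, "chi1"), rn)
    for (k in 1:3) {
      if (has(rn, paste0("chi", k)) && has(rn, paste0("chi", k + 1))) {
        add(nm(rn, paste0("chi", k)), nm(rn, paste0("chi", k + 1)), rn)
      }
    }
    if (has(rn, "psi") && has(rn + 1, "phi")) {
      add(nm(rn, "psi"), nm(rn + 1, "phi"), rn + 1)
    }
  }
  out <- if (length(pairs) == 0) {
    data.frame(a = character(), b = character(), owner = integer(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, pairs)
  }
  structure(out, class = c("torsion_adjacency", "data.frame"))
}

# histogram cell counts on equal circular bins over [-pi, pi)
.circ_counts <- function(x, bins) {
  x <- .wrap_angle(x)
  idx <- pmin(floor((x + pi) / (2 * pi / bins)) + 1L, bins)
  tabulate(idx, nbins = bins)
}

#' Histogram estimate of a circular marginal entropy
#'
#' Plug-in differential entropy on equal bins over \[-pi, pi):
#' H = -sum(p log p) + log(2 pi / bins), in units of kB (nats). The
#' Miller-Madow correction adds (occupied bins - 1) / (2 F).
#'
#' @param x numeric vector of angles (radians).
#' @param bins number of equal circular bins (default 30).
#' @param correction `"miller_madow"` (default) or `"none"`.
#' @return Entropy estimate in kB.
#' @export
marginal_entropy <- function(x, bins = 30,
                             correction = c("miller_madow", "none")) {
  correction <- match.arg(correction)
  if (length(x) == 0) stop("empty sample")
  if (length(x) < bins) {
    warning("fewer samples (", length(x), ") than bins (", bins,
            "); estimate will be strongly biased", call. = FALSE)
  }
  counts <- .circ_counts(x, bins)
  p <- counts[counts > 0] / length(x)
  H <- -sum(p * log(p)) + log(2 * pi / bins)
  if (correction == "miller_madow") {
    H <- H + (sum(counts > 0) - 1) / (2 * length(x))
  }
  H
}

#' Histogram estimate of mutual information between two circular angles
#'
#' I = H(x) + H(y) - H(x, y) on a shared bins x bins grid; the bin-width
#' terms cancel so the result is the discrete mutual information. After
#' bias correction, negative values are clipped to zero (mutual
#' information is nonnegative).
#'
#' @param x,y angle vectors (radians) of equal length.
#' @param bins bins per axis (default 30).
#' @param correction `"miller_madow"` (default) or `"none"`.
#' @return Mutual information estimate in kB, >= 0.
#' @export
mutual_information <- function(x, y, bins = 30,
                               correction = c("miller_madow", "none")) {
  correction <- match.arg(correction)
  if (length(x) != length(y)) {
    stop("length mismatch: ", length(x), " vs ", length(y))
  }
  if (length(x) == 0) stop("empty sample")
  F <- length(x)
  cx <- .circ_counts(x, bins)
  cy <- .circ_counts(y, bins)
  ix <- pmin(floor((.wrap_angle(x) + pi) / (2 * pi / bins)) + 1L, bins)
  iy <- pmin(floor((.wrap_angle(y) + pi) / (2 * pi / bins)) + 1L, bins)
  cxy <- tabulate((ix - 1L) * bins + iy, nbins = bins * bins)
  ent <- function(counts) {
    p <- counts[counts > 0] / F
    -sum(p * log(p))
  }
  I <- ent(cx) + ent(cy) - ent(cxy)
  if (correction == "miller_madow") {
    I <- I + (sum(cx > 0) - 1) / (2 * F) + (sum(cy > 0) - 1) / (2 * F) -
      (sum(cxy > 0) - 1) / (2 * F)
  }
  max(I, 0)
}

#' Per-residue partial entropies of a torsion ensemble
#'
#' The partial entropy S_i of residue i is the sum of the marginal
#' entropies of the residue's torsions minus the mutual information of
#' every adjacent torsion pair charged to the residue (see
#' [build_adjacency()]). The total configurational entropy, up to an
#' ensemble-independent constant C that cancels in all differences, is
#' the sum of the S_i.
#'
#' @param ensemble a `torsion_ensemble` with at least 2 frames.
#' @param adjacency a `torsion_adjacency`; computed from the ensemble
#'   when omitted.
#' @param bins histogram bins (default 30).
#' @param correction bias correction passed to the estimators.
#' @return An object of class `entropy_profile`: `Si` (named by residue
#'   index, kB), `total` (= sum(Si)), `sequence`, and estimator metadata.
#' @export
partial_entropies <- function(ensemble, adjacency = NULL, bins = 30,
                              correction = c("miller_madow", "none")) {
  correction <- match.arg(correction)
  if (nrow(ensemble$samples) < 2) {
    stop("entropy estimation needs an ensemble of at least 2 frames")
  }
  if (is.null(adjacency)) adjacency <- build_adjacency(ensemble)
  lab <- ensemble$labels
  nres <- nchar(ensemble$sequence)
  Si <- stats::setNames(numeric(nres), seq_len(nres))
  marg <- apply(ensemble$samples, 2, marginal_entropy, bins = bins,
                correction = correction)
  for (rn in seq_len(nres)) {
    cols <- paste0(lab$torsion[lab$resno == rn], "_", rn)
    if (length(cols) == 0) next
    Si[rn] <- sum(marg[cols])
  }
  if (nrow(adjacency) > 0) {
    for (k in seq_len(nrow(adjacency))) {
      I <- mutual_information(ensemble$samples[, adjacency$a[k]],
                              ensemble$samples[, adjacency$b[k]],
                              bins = bins, correction = correction)
      ow <- as.character(adjacency$owner[k])
      Si[ow] <- Si[ow] - I
    }
  }
  empty <- setdiff(seq_len(nres), unique(lab$resno))
  if (length(empty) > 0) {
    warning("residue(s) ", paste(empty, collapse = ", "),
            " have no torsions; S_i set to 0", call. = FALSE)
  }
  structure(
    list(Si = Si, total = sum(Si), sequence = ensemble$sequence,
         meta = list(bins = bins, frames = nrow(ensemble$samples),
                     correction = correction)),
    class = "entropy_profile"
  )
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat("entropy_profile:", length(x$Si), "residues,",
      x$meta$frames, "frames,", x$meta$bins, "bins (",
      x$meta$correction, ")\n")
  cat("  total Sconf + C =", format(x$total, digits = 6), "kB\n")
  invisible(x)
}

#' @export
summary.entropy_profile <- function(object, ...) {
  print(object)
  cat("  per-residue S_i (kB): min", format(min(object$Si), digits = 4),
      "median", format(stats::median(object$Si), digits = 4),
      "max", format(max(object$Si), digits = 4), "\n")
  invisible(object)
}

#' @export
as.data.frame.entropy_profile <- function(x, ...) {
  data.frame(resno = as.integer(names(x$Si)),
             restype = strsplit(x$sequence, "")[[1]][seq_along(x$Si)],
             Si_kB = as.numeric(x$Si))
}

#' @export
plot.entropy_profile <- function(x, ...) {
  graphics::barplot(x$Si, names.arg = names(x$Si),
                    xlab = "residue", ylab = expression(S[i] ~ (k[B])), ...)
  invisible(x)
}

#' Per-residue entropy difference between two profiles
#'
#' The unknown additive constant C of each total cancels in the
#' difference, so delta S_i and their sum are directly comparable
#' between conformations of the same sequence.
#'
#' @param A,B `entropy_profile` objects over the same sequence.
#' @return An object of class `entropy_difference`: `deltaSi` (A minus
#'   B, kB), `total`, `sequence`.
#' @export
entropy_difference <- function(A, B) {
  if (!identical(A$sequence, B$sequence)) {
    stop("profiles are over different sequences")
  }
  if (length(A$Si) != length(B$Si)) {
    stop("profile length mismatch: ", length(A$Si), " vs ", length(B$Si))
  }
  d <- A$Si - B$Si
  structure(
    list(deltaSi = d, total = sum(d), sequence = A$sequence),
    class = "entropy_difference"
  )
}

#' @export
print.entropy_difference <- function(x, ...) {
  cat("entropy_difference:", length(x$deltaSi), "residues, total",
      format(x$total, digits = 6), "kB\n")
  invisible(x)
}

#' @export
plot.entropy_difference <- function(x, ...) {
  graphics::barplot(x$deltaSi, names.arg = names(x$deltaSi),
                    xlab = "residue",
                    ylab = expression(Delta * S[i] ~ (k[B])), ...)
  invisible(x)
}

#' Entropy carried by a residue segment
#'
#' @param d an `entropy_difference` (or `entropy_profile`).
#' @param from,to inclusive 1-based residue range.
#' @return List with `sum` (kB) and `fraction` of the profile total.
#' @export
segment_sum <- function(d, from, to) {
  v <- if (inherits(d, "entropy_difference")) d$deltaSi else d$Si
  if (from < 1 || to > length(v) || from > to) {
    stop("invalid residue range ", from, "-", to)
  }
  s <- sum(v[from:to])
  list(sum = s, fraction = s / sum(v))
}

#' Convert an entropy to its free-energy contribution -T S
#'
#' @param S entropy in kB (nats).
#' @param T temperature in Kelvin (default 300).
#' @return -T*S in kcal/mol (kB = 0.0019872 kcal/(mol K)); 1 kB at 300 K
#'   is -0.596 kcal/mol.
#' @export
entropy_to_free_energy <- function(S, T = 300) {
  -T * S * .kB
}
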