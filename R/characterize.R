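# Structure comparison and descriptors: Kabsch RMSD, UPGMA deduplication,
# contact maps, radius of gyration, Shrake-Rupley SASA, simplified
# secondary structure.

# matched coordinate matrices for two models under an atom selection
.matched_coords <- function(A, B, select = c("CA", "backbone", "all")) {
  select <- match.arg(select)
  pick <- function(m) {
    a <- m$atoms
    keep <- switch(select,
      CA = a$name == "CA",
      backbone = a$name %in% c("N", "CA", "C", "O"),
      all = rep(TRUE, nrow(a))
    )
    a <- a[keep, , drop = FALSE]
    key <- paste(a$chain, a$resno, a$name)
    list(xyz = as.matrix(a[, c("x", "y", "z")]), key = key)
  }
  pa <- pick(A); pb <- pick(B)
  shared <- intersect(pa$key, pb$key)
  if (select != "all" && (length(shared) != length(pa$key) ||
                          length(shared) != length(pb$key))) {
    stop("atom selections do not match between structures (",
         length(pa$key), " vs ", length(pb$key), " atoms, ",
         length(shared), " shared)")
  }
  if (length(shared) < 3) stop("need at least 3 matched atoms")
  list(A = pa$xyz[match(shared, pa$key), , drop = FALSE],
       B = pb$xyz[match(shared, pb$key), , drop = FALSE])
}

#' Minimal RMSD after Kabsch superposition
#'
#' Least-squares rigid-body superposition via singular value
#' decomposition, with the reflection branch corrected so the rotation is
#' proper (determinant +1).
#'
#' @param A,B `structure_model` objects.
#' @param select atom selection: `"CA"` (default), `"backbone"`, or
#'   `"all"` (all atoms shared by name between the two structures).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(A, B, select = c("CA", "backbone", "all")) {
  mc <- .matched_coords(A, B, select)
  P <- scale(mc$A, scale = FALSE)
  Q <- scale(mc$B, scale = FALSE)
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  diffs <- Q - P %*% t(R)
  sqrt(mean(rowSums(diffs^2)))
}

#' Pairwise RMSD matrix over a set of structures
#'
#' @param models a `structure_ensemble` or named list of
#'   `structure_model` objects.
#' @param select atom selection passed to [kabsch_rmsd()].
#' @return A symmetric zero-diagonal matrix (Angstrom) of class
#'   `distance_matrix`. RMSD after independent superpositions need not
#'   satisfy the triangle inequality.
#' @export
rmsd_matrix <- function(models, select = "CA") {
  n <- length(models)
  labels <- names(models)
  if (is.null(labels)) labels <- paste0("conf", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        D[i, j] <- D[j, i] <- kabsch_rmsd(models[[i]], models[[j]], select)
      }
    }
  }
  class(D) <- c("distance_matrix", class(D))
  D
}

# run body with a private RNG stream, restoring the caller's afterwards
.with_seed <- function(seed, body) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  body
}

#' Deduplicate conformations by average-linkage (UPGMA) clustering
#'
#' Agglomerates while the smallest average-linkage distance is below the
#' threshold; each cluster is then reduced to a single representative
#' drawn uniformly at random under the given seed. Groups of mutually
#' similar decoys (RMSD below the threshold) thus collapse to one member.
#'
#' @param D symmetric distance matrix with labelled rows/columns
#'   (Angstrom), e.g. from [rmsd_matrix()].
#' @param threshold cluster separation criterion in Angstrom (default 5).
#' @param seed integer seed for the representative draw.
#' @return An object of class `cluster_result`: `clusters` (named list of
#'   label vectors), `representatives`, `threshold`, `seed`.
#' @export
upgma_dedup <- function(D, threshold = 5, seed = 1L) {
  D <- as.matrix(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("conf", seq_len(nrow(D)))
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    stop("distance matrix not symmetric")
  }
  n <- nrow(D)
  if (n == 1) {
    member <- stats::setNames(1L, labels)
  } else {
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    below <- hc$height[hc$height < threshold]
    member <- if (length(below) == 0) {
      stats::setNames(seq_len(n), labels)
    } else {
      stats::cutree(hc, h = max(below))
    }
  }
  clusters <- split(labels, member)
  names(clusters) <- paste0("cluster", seq_along(clusters))
  reps <- .with_seed(seed, vapply(clusters, function(members) {
    members[sample.int(length(members), 1)]
  }, character(1)))
  structure(
    list(clusters = clusters, representatives = unname(reps),
         threshold = threshold, seed = as.integer(seed)),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", length(x$clusters), "clusters at threshold",
      x$threshold, "A (seed", paste0(x$seed, ")"), "\n")
  for (i in seq_along(x$clusters)) {
    cat("  ", names(x$clusters)[i], ": {",
        paste(x$clusters[[i]], collapse = ", "), "} rep = ",
        x$representatives[i], "\n", sep = "")
  }
  invisible(x)
}

#' C-alpha contact map
#'
#' @param S a `structure_model`; every residue must have a CA atom.
#' @return Symmetric Nres x Nres matrix of CA-CA distances (Angstrom),
#'   zero diagonal, dimnames = residue numbers.
#' @export
contact_map <- function(S) {
  res <- S$residues
  ca <- matrix(NA_real_, nrow(res), 3)
  for (i in seq_len(nrow(res))) {
    p <- .atom_xyz(S, res$chain[i], res$resno[i], "CA")
    if (is.null(p)) stop("residue ", res$resno[i], " (", res$resid[i],
                         ") has no CA atom")
    ca[i, ] <- p
  }
  M <- as.matrix(stats::dist(ca))
  dimnames(M) <- list(res$resno, res$resno)
  M
}

#' Radius of gyration
#'
#' Unweighted root-mean-square distance of the atoms from their centroid;
#' invariant under rigid motion.
#'
#' @param S a `structure_model`.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(S) {
  xyz <- as.matrix(S$atoms[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the structure by testing quasi-uniform
#' surface points on each atom's expanded sphere against all neighbour
#' spheres. Radii: C 1.70, N 1.55, O 1.52, S 1.80 Angstrom.
#'
#' @param S a `structure_model`.
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param n_points surface points per atom (960 default; 92 for speed).
#' @param default_radius radius for elements absent from the built-in
#'   table; if `NA` (default) an unknown element is an error.
#' @return List with `total` (Angstrom^2), `per_residue` (named vector,
#'   sums to total) and `per_atom`.
#' @export
sasa_shrake_rupley <- function(S, probe = 1.4, n_points = 960,
                               default_radius = NA) {
  a <- S$atoms
  radii <- .VDW_RADII[a$element]
  if (anyNA(radii)) {
    if (is.na(default_radius)) {
      stop("unknown element(s): ",
           paste(unique(a$element[is.na(radii)]), collapse = ", "),
           "; set default_radius to proceed")
    }
    radii[is.na(radii)] <- default_radius
  }
  xyz <- as.matrix(a[, c("x", "y", "z")])
  ext <- radii + probe
  pts <- .sphere_points(n_points)
  n <- nrow(xyz)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nbr <- which(d2 < (ext[i] + ext)^2 & seq_len(n) != i)
    surf <- sweep(pts * ext[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nbr) {
      acc <- acc & rowSums(sweep(surf, 2, xyz[j, ])^2) > ext[j]^2
      if (!any(acc)) break
    }
    per_atom[i] <- 4 * pi * ext[i]^2 * mean(acc)
  }
  rkey <- paste(a$chain, a$resno)
  per_res <- tapply(per_atom, factor(rkey, levels = unique(rkey)), sum)
  list(total = sum(per_atom),
       per_residue = stats::setNames(as.numeric(per_res),
                                     S$residues$resno),
       per_atom = per_atom)
}

# backbone amide H position, DSSP convention: 1 A from N along the
# C(i-1)->O(i-1) bond direction reversed
.amide_h <- function(S, i) {
  res <- S$residues
  if (i < 2 || res$chain[i] != res$chain[i - 1]) return(NULL)
  n <- .atom_xyz(S, res$chain[i], res$resno[i], "N")
  cp <- .atom_xyz(S, res$chain[i - 1], res$resno[i - 1], "C")
  op <- .atom_xyz(S, res$chain[i - 1], res$resno[i - 1], "O")
  if (is.null(n) || is.null(cp) || is.null(op)) return(NULL)
  d <- cp - op
  n + d / sqrt(sum(d^2))
}

#' Simplified secondary-structure assignment
#'
#' Backbone hydrogen bonds are scored with the Kabsch-Sander
#' electrostatic energy E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)
#' kcal/mol (bond if E < -0.5). Two consecutive i -> i+4 turns mark a
#' helix (H); reciprocal long-range bonds mark extended bridges (E);
#' everything else is coil (C). This is a descriptive three-state
#' assignment, not a full DSSP implementation.
#'
#' @param S a `structure_model` with backbone N, CA, C, O atoms.
#' @return Character vector of per-residue labels in `{"H","E","C"}`.
#' @export
secondary_structure <- function(S) {
  res <- S$residues
  n <- nrow(res)
  labels <- rep("C", n)
  if (n < 5) return(labels)
  geta <- function(i, nm) .atom_xyz(S, res$chain[i], res$resno[i], nm)
  has_o <- vapply(seq_len(n), function(i) !is.null(geta(i, "O")), logical(1))
  if (!all(has_o)) {
    warning("residue(s) ", paste(res$resno[!has_o], collapse = ", "),
            " missing O; labelled C", call. = FALSE)
  }
  # hbond[d, a]: TRUE when NH of donor d bonds CO of acceptor a
  hb <- matrix(FALSE, n, n)
  for (d in seq_len(n)) {
    h <- .amide_h(S, d)
    nn <- geta(d, "N")
    if (is.null(h) || is.null(nn)) next
    for (a in seq_len(n)) {
      if (abs(d - a) < 3 || !has_o[a]) next
      o <- geta(a, "O"); cc <- geta(a, "C")
      if (is.null(o) || is.null(cc)) next
      rON <- sqrt(sum((o - nn)^2)); rCH <- sqrt(sum((cc - h)^2))
      rOH <- sqrt(sum((o - h)^2)); rCN <- sqrt(sum((cc - nn)^2))
      E <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      hb[d, a] <- E < -0.5
    }
  }
  turn4 <- vapply(seq_len(n - 4), function(i) hb[i + 4, i], logical(1))
  for (i in seq_len(n - 5)) {
    if (turn4[i] && turn4[i + 1]) labels[(i + 1):(i + 4)] <- "H"
  }
  for (i in seq_len(n)) {
    if (labels[i] == "H") next
    far <- which(abs(seq_len(n) - i) >= 5)
    if (any(hb[i, far] & hb[far, i])) labels[i] <- "E"
  }
  labels
}
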