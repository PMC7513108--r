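# Synthetic inputs with known ground truth: ideal-geometry chains built
# from torsion targets, torsion ensembles with analytic entropy, decoy
# sets with planted near-duplicates, and energy tables with planted gaps.

# place atom D given A, B, C with bond |C-D|, angle B-C-D and torsion
# A-B-C-D (natural extension of reference frame)
.nerf <- function(A, B, C, bond, angle, torsion) {
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) stop("impossible geometry: collinear reference atoms")
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(torsion),
          bond * sin(angle) * sin(torsion))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# CB direction from placed N, CA, C: tetrahedral branch off the backbone
.place_cb <- function(N, CA, C, bond = .IDEAL_GEOM$b_CA_CB) {
  u1 <- (N - CA) / sqrt(sum((N - CA)^2))
  u2 <- (C - CA) / sqrt(sum((C - CA)^2))
  b <- -(u1 + u2)
  b <- b / sqrt(sum(b^2))
  n <- c(u1[2] * u2[3] - u1[3] * u2[2],
         u1[3] * u2[1] - u1[1] * u2[3],
         u1[1] * u2[2] - u1[2] * u2[1])
  n <- n / sqrt(sum(n^2))
  # solve d.u1 = cos(ang) with d = alpha*b + beta*n, using n.u1 = 0
  ang <- .deg2rad(.IDEAL_GEOM$a_N_CA_CB)
  alpha <- cos(ang) / sum(b * u1)
  beta <- sqrt(max(1 - alpha^2, 0))
  d <- alpha * b + beta * n
  CA + bond * d / sqrt(sum(d^2))
}

#' Build an ideal-geometry chain from torsion targets
#'
#' Forward kinematics with ideal bond lengths (N-CA 1.458, CA-C 1.525,
#' C-N 1.329 Angstrom) and angles, omega fixed at 180 degrees. Carbonyl
#' O and (for non-glycine) CB atoms are placed geometrically. The
#' construction round-trips: [compute_torsions()] on the result recovers
#' the targets.
#'
#' @param sequence one-letter amino-acid sequence.
#' @param phi,psi numeric vectors of torsion targets in radians, length
#'   `nchar(sequence)`; `phi[1]` and `psi[n]` are not used (chain ends).
#' @param chain chain identifier.
#' @return A `structure_model`.
#' @export
build_chain <- function(sequence, phi, psi, chain = "A") {
  n <- nchar(sequence)
  if (n < 1) stop("empty sequence")
  if (length(phi) != n || length(psi) != n) {
    stop("phi/psi must have length ", n)
  }
  aa1 <- strsplit(sequence, "")[[1]]
  aa3 <- bio3d::aa123(aa1)
  g <- .IDEAL_GEOM
  aNCAC <- .deg2rad(g$a_N_CA_C); aCACN <- .deg2rad(g$a_CA_C_N)
  aCNCA <- .deg2rad(g$a_C_N_CA); omega <- .deg2rad(g$omega)
  N <- vector("list", n); CA <- vector("list", n); C <- vector("list", n)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$b_N_CA, 0, 0)
  C[[1]] <- CA[[1]] + g$b_CA_C * c(cos(pi - aNCAC), sin(pi - aNCAC), 0)
  for (i in seq_len(n - 1)) {
    if (!is.finite(psi[i])) stop("psi[", i, "] must be finite")
    N[[i + 1]] <- .nerf(N[[i]], CA[[i]], C[[i]], g$b_C_N, aCACN, psi[i])
    CA[[i + 1]] <- .nerf(CA[[i]], C[[i]], N[[i + 1]], g$b_N_CA, aCNCA, omega)
    if (!is.finite(phi[i + 1])) stop("phi[", i + 1, "] must be finite")
    C[[i + 1]] <- .nerf(C[[i]], N[[i + 1]], CA[[i + 1]], g$b_CA_C, aNCAC,
                        phi[i + 1])
  }
  rows <- list()
  add <- function(nm, el, i, p) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = nm, element = el, resno = i, resid = aa3[i], chain = chain,
      x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(n)) {
    add("N", "N", i, N[[i]])
    add("CA", "C", i, CA[[i]])
    add("C", "C", i, C[[i]])
    # O anti to the next N along the CA-C axis; last residue uses psi = pi
    psi_i <- if (i < n) psi[i] else if (is.finite(psi[n])) psi[n] else pi
    O <- .nerf(N[[i]], CA[[i]], C[[i]], g$b_C_O, .deg2rad(g$a_CA_C_O),
               psi_i + pi)
    add("O", "O", i, O)
    if (aa1[i] != "G") add("CB", "C", i, .place_cb(N[[i]], CA[[i]], C[[i]]))
  }
  structure_model(do.call(rbind, rows))
}

# von Mises quantile by dense-grid CDF inversion (monotone, deterministic)
.qvonmises <- function(u, mu, kappa, ngrid = 8192) {
  theta <- seq(-pi, pi, length.out = ngrid + 1)
  dens <- exp(kappa * cos(theta - mu)) / (2 * pi * besselI(kappa, 0))
  cdf <- c(0, cumsum((dens[-1] + dens[-(ngrid + 1)]) / 2 *
                       diff(theta)))
  cdf <- cdf / cdf[ngrid + 1]
  stats::approx(cdf, theta, xout = u, ties = "ordered")$y
}

#' Analytic entropy of a von Mises marginal
#'
#' H = log(2 pi I0(kappa)) - kappa I1(kappa) / I0(kappa), in kB.
#'
#' @param kappa concentration parameter (0 gives the uniform circle,
#'   log(2 pi)).
#' @return Entropy in kB.
#' @export
vonmises_entropy <- function(kappa) {
  if (kappa == 0) return(log(2 * pi))
  log(2 * pi * besselI(kappa, 0)) -
    kappa * besselI(kappa, 1) / besselI(kappa, 0)
}

#' Mutual information of a Gaussian-copula coupled pair
#'
#' -0.5 log(1 - rho^2); invariant under the monotone marginal transforms
#' used by the sampler, so it is exact for any marginals.
#'
#' @param rho copula correlation in (-1, 1).
#' @return Mutual information in kB.
#' @export
copula_mi <- function(rho) {
  if (abs(rho) >= 1) stop("rho must lie strictly inside (-1, 1)")
  -0.5 * log(1 - rho^2)
}

#' Sample a torsion ensemble with known analytic entropy
#'
#' Marginals are uniform or von Mises; designated pairs are coupled
#' through a Gaussian copula with correlation `rho`, which leaves the
#' marginals intact and contributes exactly -0.5 log(1 - rho^2) of
#' mutual information per pair. Coupled pairs must be disjoint so the
#' analytic total (sum of marginal entropies minus pair MIs) is exact.
#'
#' @param marginals named list, one entry per torsion label (e.g.
#'   `"phi_2"`): either `list(type = "uniform")` or
#'   `list(type = "vonmises", mu = 0, kappa = 2)`.
#' @param frames number of frames F.
#' @param coupled optional data.frame with columns `a`, `b` (labels) and
#'   `rho`.
#' @param seed integer seed; generation is a pure function of it.
#' @param sequence optional one-letter sequence (defaults to poly-A of
#'   the largest residue index).
#' @return List: `ensemble` (a `torsion_ensemble`), `analytic_total`
#'   (kB), `analytic_marginals`, `analytic_mi`.
#' @export
sample_torsion_ensemble <- function(marginals, frames, coupled = NULL,
                                    seed = 1L, sequence = NULL) {
  labels <- names(marginals)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("marginals must be a uniquely named list of torsion labels")
  }
  if (!is.null(coupled) && nrow(coupled) > 0) {
    used <- c(coupled$a, coupled$b)
    if (anyDuplicated(used)) {
      stop("coupled pairs must be disjoint (each torsion in at most one pair)")
    }
    if (!all(used %in% labels)) {
      stop("coupled pair references unknown torsion label")
    }
    if (any(abs(coupled$rho) >= 1)) {
      stop("rho must lie strictly inside (-1, 1)")
    }
  }
  T_ <- length(labels)
  .with_seed(seed, {
    z <- matrix(stats::rnorm(frames * T_), nrow = frames,
                dimnames = list(NULL, labels))
    if (!is.null(coupled) && nrow(coupled) > 0) {
      for (k in seq_len(nrow(coupled))) {
        a <- coupled$a[k]; b <- coupled$b[k]; rho <- coupled$rho[k]
        z[, b] <- rho * z[, a] + sqrt(1 - rho^2) * z[, b]
      }
    }
    u <- stats::pnorm(z)
    x <- matrix(NA_real_, frames, T_, dimnames = list(NULL, labels))
    Hm <- stats::setNames(numeric(T_), labels)
    for (lab in labels) {
      m <- marginals[[lab]]
      if (m$type == "uniform") {
        x[, lab] <- 2 * pi * u[, lab] - pi
        Hm[lab] <- log(2 * pi)
      } else if (m$type == "vonmises") {
        x[, lab] <- .qvonmises(u[, lab], m$mu, m$kappa)
        Hm[lab] <- vonmises_entropy(m$kappa)
      } else {
        stop("unknown marginal type: ", m$type)
      }
    }
    mi <- if (is.null(coupled) || nrow(coupled) == 0) 0 else
      sum(vapply(coupled$rho, copula_mi, numeric(1)))
    ens <- torsion_ensemble(x, sequence = sequence)
    list(ensemble = ens,
         analytic_total = sum(Hm) - mi,
         analytic_marginals = Hm,
         analytic_mi = mi)
  })
}

#' Generate a synthetic decoy set with planted near-duplicates
#'
#' Builds `n` ideal-geometry conformations of one sequence from
#' perturbed phi/psi targets. The last `n_duplicates` structures are
#' near-copies (tiny perturbation) of decoy `dup_target`, so
#' average-linkage deduplication at a few Angstrom collapses them.
#'
#' @param sequence one-letter sequence (>= 10 residues recommended so
#'   distinct decoys separate well).
#' @param n total number of structures.
#' @param n_duplicates how many of the `n` are near-copies of
#'   `dup_target`.
#' @param dup_target index of the duplicated decoy.
#' @param perturb sd (radians) of the phi/psi perturbation between
#'   distinct decoys.
#' @param dup_perturb sd (radians) within a duplicate group.
#' @param seed integer seed; output is bit-reproducible.
#' @return Named `structure_ensemble` (`decoy1`, `decoy2`, ...).
#' @export
make_decoy_set <- function(sequence, n, n_duplicates = 0, dup_target = 1,
                           perturb = 1.0, dup_perturb = 0.005, seed = 1L) {
  if (n < 2) stop("need at least 2 decoys")
  n_distinct <- n - n_duplicates
  if (dup_target > n_distinct) stop("dup_target must index a distinct decoy")
  nres <- nchar(sequence)
  .with_seed(seed, {
    base_phi <- rep(-.deg2rad(57), nres)
    base_psi <- rep(-.deg2rad(47), nres)
    targets <- vector("list", n)
    for (i in seq_len(n_distinct)) {
      targets[[i]] <- list(
        phi = .wrap_angle(base_phi + stats::rnorm(nres, sd = perturb)),
        psi = .wrap_angle(base_psi + stats::rnorm(nres, sd = perturb))
      )
    }
    if (n_duplicates > 0) {
      for (i in seq(n_distinct + 1, n)) {
        targets[[i]] <- list(
          phi = .wrap_angle(targets[[dup_target]]$phi +
                              stats::rnorm(nres, sd = dup_perturb)),
          psi = .wrap_angle(targets[[dup_target]]$psi +
                              stats::rnorm(nres, sd = dup_perturb))
        )
      }
    }
    models <- lapply(targets, function(tg) {
      build_chain(sequence, tg$phi, tg$psi)
    })
    names(models) <- paste0("decoy", seq_len(n))
    structure(models, class = "structure_ensemble")
  })
}

#' Generate an energy table with planted gaps
#'
#' Emulates the head-to-head scenario of a native state against decoys:
#' a designated winner sits at the origin and every other conformation
#' is displaced by planted gaps in Eintra, Gsolv and -TSconf (kcal/mol),
#' plus optional Gaussian noise. A rival with a negative planted
#' `dG0` but a large `dminusTS` reproduces the entropic-reversal
#' scenario: it wins under G0 yet loses under Ghat.
#'
#' @param n number of conformations.
#' @param winner index of the designated winner (default 1).
#' @param dEintra,dGsolv,dminusTS numeric vectors of length `n`: planted
#'   offsets relative to the winner (entries at `winner` are forced to 0).
#' @param noise_sd sd of additive Gaussian noise on each term.
#' @param seed integer seed.
#' @return An `energy_table` with rows `CONF1..CONFn`.
#' @export
make_energy_table <- function(n, winner = 1, dEintra = numeric(n),
                              dGsolv = numeric(n), dminusTS = numeric(n),
                              noise_sd = 0, seed = 1L) {
  stopifnot(length(dEintra) == n, length(dGsolv) == n,
            length(dminusTS) == n, winner >= 1, winner <= n)
  dEintra[winner] <- 0; dGsolv[winner] <- 0; dminusTS[winner] <- 0
  .with_seed(seed, {
    noise <- function() if (noise_sd > 0) stats::rnorm(n, sd = noise_sd)
      else numeric(n)
    energy_table(data.frame(
      name = paste0("CONF", seq_len(n)),
      Eintra = dEintra + noise(),
      Gsolv = dGsolv + noise(),
      minusTSconf = dminusTS + noise(),
      stringsAsFactors = FALSE
    ))
  })
}
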