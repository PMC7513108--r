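# Shared fixture builders: hand-written PDB text, ad-hoc models, rigid
# motions, and a brute-force superposition oracle.

# one correctly column-aligned ATOM record
pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1.0, b = 0.0, element = substr(name, 1, 1),
                          alt = " ") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s%s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, alt, resid, chain, resno, x, y, z, occ, b, element)
}

# 3-residue ALA chain as PDB text (geometry arbitrary but non-degenerate)
pdb_three_residue_text <- function() {
  lines <- character(0)
  s <- 0
  for (i in 1:3) {
    base <- (i - 1) * 3.5
    s <- s + 1; lines <- c(lines, pdb_atom_line(s, "N", "ALA", "A", i, base, 0, 0))
    s <- s + 1; lines <- c(lines, pdb_atom_line(s, "CA", "ALA", "A", i, base + 1.2, 0.9, 0, element = "C"))
    s <- s + 1; lines <- c(lines, pdb_atom_line(s, "C", "ALA", "A", i, base + 2.4, 0.2, 0.4))
    s <- s + 1; lines <- c(lines, pdb_atom_line(s, "O", "ALA", "A", i, base + 2.5, -0.9, 0.9))
  }
  c(lines, "END")
}

write_pdb_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# bare structure_model from a coordinate matrix of CA pseudo-atoms
point_model <- function(xyz, element = "C") {
  xyz <- as.matrix(xyz)
  structure_model(data.frame(
    name = "CA", element = element, resno = seq_len(nrow(xyz)),
    resid = "ALA", chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE
  ))
}

# random proper rotation matrix from a quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2
  ), 3, 3, byrow = TRUE)
}

apply_rigid <- function(model, R, t = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  model$atoms$x <- xyz[, 1] + t[1]
  model$atoms$y <- xyz[, 2] + t[2]
  model$atoms$z <- xyz[, 3] + t[3]
  model
}

# brute-force minimal RMSD over proper rotations: random quaternion
# search plus Nelder-Mead refinement on the rotation vector
brute_force_rmsd <- function(A, B, n_start = 2000) {
  P <- scale(A, scale = FALSE)
  Q <- scale(B, scale = FALSE)
  obj_R <- function(R) sqrt(mean(rowSums((Q - P %*% t(R))^2)))
  rotvec <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    k <- v / th
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
                3, 3, byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  best <- Inf; best_v <- c(0, 0, 0)
  for (i in seq_len(n_start)) {
    v <- runif(3, -pi, pi)
    f <- obj_R(rotvec(v))
    if (f < best) { best <- f; best_v <- v }
  }
  opt <- optim(best_v, function(v) obj_R(rotvec(v)),
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

helix_model <- function(n = 10, sequence = strrep("A", n)) {
  build_chain(sequence, rep(-57 * pi / 180, n), rep(-47 * pi / 180, n))
}

# hand-made entropy profile for difference/segment arithmetic
fake_profile <- function(Si, sequence = strrep("A", length(Si))) {
  structure(list(Si = stats::setNames(Si, seq_along(Si)),
                 total = sum(Si), sequence = sequence,
                 meta = list(bins = 30, frames = NA,
                             correction = "miller_madow")),
            class = "entropy_profile")
}
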