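# PDB reading, dihedral geometry and torsion extraction

test_that("read_pdb parses a hand-written chain and multi-model files", {
  path <- write_pdb_text(pdb_three_residue_text())
  m <- read_pdb(path)
  expect_s3_class(m, "structure_model")
  expect_equal(n_residues(m), 3)
  expect_equal(m$sequence, "AAA")
  expect_false(any(m$residues$incomplete))

  body <- pdb_three_residue_text()
  body <- body[body != "END"]
  two <- c("MODEL        1", body, "ENDMDL",
           "MODEL        2", body, "ENDMDL", "END")
  ens <- read_pdb(write_pdb_text(two), policy = "all")
  expect_s3_class(ens, "structure_ensemble")
  expect_length(ens, 2)
  expect_identical(ens[[1]]$sequence, ens[[2]]$sequence)
  expect_identical(ens[[1]]$atoms$name, ens[[2]]$atoms$name)

  first <- read_pdb(write_pdb_text(two), policy = "first")
  expect_s3_class(first, "structure_model")
})

test_that("read_pdb flags incomplete residues and rejects bad input", {
  lines <- pdb_three_residue_text()
  lines <- lines[!grepl("CA  ALA A   2", lines)]  # drop CA of residue 2
  m <- read_pdb(write_pdb_text(lines))
  expect_true(m$residues$incomplete[2])
  expect_false(m$residues$incomplete[1])
  # torsions involving the incomplete residue are undefined
  te <- compute_torsions(m)
  expect_false(any(te$labels$resno == 2))

  bad <- pdb_three_residue_text()
  bad[3] <- substr(bad[3], 1, 40)  # truncated record
  expect_error(read_pdb(write_pdb_text(bad)), "line 3")
  expect_error(read_pdb(write_pdb_text("END")), "empty structure")
})

test_that("alternate locations resolve to highest occupancy, ties first", {
  lines <- c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.0, 0, 0, occ = 0.4,
                  element = "C", alt = "A"),
    pdb_atom_line(3, "CA", "ALA", "A", 1, 9.0, 0, 0, occ = 0.6,
                  element = "C", alt = "B"),
    pdb_atom_line(4, "C", "ALA", "A", 1, 2.0, 1, 0),
    "END"
  )
  m <- read_pdb(write_pdb_text(lines))
  ca <- m$atoms[m$atoms$name == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 9.0)
})

test_that("dihedral matches the IUPAC convention on planar and chiral cases", {
  # planar syn (U-shape): terminal bonds eclipse -> 0
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), 0)
  # planar anti (zigzag) -> pi
  expect_equal(abs(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0))),
               pi)
  # right-handed quarter turn, by the explicit normal-vector formula
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)),
               pi / 2)
  # mirroring flips the sign
  mir <- function(p) c(p[1], p[2], -p[3])
  expect_equal(dihedral(mir(c(0, 0, 0)), mir(c(1, 0, 0)), mir(c(1, 1, 0)),
                        mir(c(1, 1, 1))), -pi / 2)
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0), c(1, 1, 1)),
               "coincident")
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("dihedral is rigid-motion invariant and obeys the reversal relation", {
  set.seed(42)
  for (i in 1:25) {
    pts <- lapply(1:4, function(j) rnorm(3))
    d0 <- tryCatch(dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]]),
                   error = function(e) NULL)
    if (is.null(d0)) next
    R <- random_rotation(); t <- rnorm(3, sd = 5)
    moved <- lapply(pts, function(p) as.numeric(R %*% p) + t)
    expect_equal(dihedral(moved[[1]], moved[[2]], moved[[3]], moved[[4]]),
                 d0, tolerance = 1e-9)
    expect_equal(dihedral(pts[[4]], pts[[3]], pts[[2]], pts[[1]]), d0,
                 tolerance = 1e-9)
  }
})

test_that("compute_torsions applies chain-end rules and round-trips the builder", {
  m <- helix_model(10)
  te <- compute_torsions(m)
  expect_false("phi_1" %in% colnames(te$samples))
  expect_false("psi_10" %in% colnames(te$samples))
  expect_equal(unname(te$samples[1, grep("^phi", colnames(te$samples))]),
               rep(-57 * pi / 180, 9), tolerance = 1e-6)
  expect_equal(unname(te$samples[1, grep("^psi", colnames(te$samples))]),
               rep(-47 * pi / 180, 9), tolerance = 1e-6)

  two <- build_chain("GG", c(NA, 1.0), c(2.0, NA))
  t2 <- compute_torsions(two)
  expect_setequal(colnames(t2$samples), c("psi_1", "phi_2"))

  # values agree with the bio3d torsion implementation (degrees)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, f)
  ref <- bio3d::torsion.pdb(bio3d::read.pdb(f, verbose = FALSE))
  expect_equal(unname(te$samples[1, "phi_5"]) * 180 / pi,
               unname(ref$phi[5]), tolerance = 0.1)
  expect_equal(unname(te$samples[1, "psi_5"]) * 180 / pi,
               unname(ref$psi[5]), tolerance = 0.1)
})

test_that("multi-model ensembles keep frames aligned and detect mismatches", {
  base <- helix_model(6)
  pert <- build_chain(strrep("A", 6),
                      rep(-57 * pi / 180, 6) + c(0, 0.2, 0, 0, 0, 0),
                      rep(-47 * pi / 180, 6))
  ens <- structure(list(base, base, pert, base, base),
                   class = "structure_ensemble")
  te <- compute_torsions(ens)
  expect_equal(nrow(te$samples), 5)
  same <- apply(te$samples, 2, function(col) col[1] == col[2])
  expect_true(all(same))
  expect_false(all(te$samples[3, ] == te$samples[1, ]))

  other <- build_chain("AAAAAG", rep(-1, 6), rep(2, 6))
  expect_error(compute_torsions(list(base, other)), "sequence")
})

test_that("chi torsions come from side-chain atoms and chain ends omit phi/psi", {
  # serine with an OG atom gives exactly one chi
  lines <- c(
    pdb_atom_line(1, "N", "SER", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "SER", "A", 1, 1.458, 0, 0, element = "C"),
    pdb_atom_line(3, "C", "SER", "A", 1, 2.0, 1.4, 0),
    pdb_atom_line(4, "O", "SER", "A", 1, 1.5, 2.5, 0),
    pdb_atom_line(5, "CB", "SER", "A", 1, 2.0, -0.8, 1.2, element = "C"),
    pdb_atom_line(6, "OG", "SER", "A", 1, 1.6, -2.1, 1.4),
    pdb_atom_line(7, "N", "SER", "A", 2, 3.3, 1.5, 0.4),
    pdb_atom_line(8, "CA", "SER", "A", 2, 4.2, 2.6, 0.7, element = "C"),
    pdb_atom_line(9, "C", "SER", "A", 2, 5.6, 2.1, 1.1),
    pdb_atom_line(10, "O", "SER", "A", 2, 5.9, 0.9, 1.1),
    "END"
  )
  m <- suppressWarnings(read_pdb(write_pdb_text(lines)))
  te <- suppressWarnings(compute_torsions(m))
  expect_true("chi1_1" %in% colnames(te$samples))
  ref <- dihedral(c(0, 0, 0), c(1.458, 0, 0), c(2.0, -0.8, 1.2),
                  c(1.6, -2.1, 1.4))
  expect_equal(unname(te$samples[1, "chi1_1"]), ref, tolerance = 1e-9)
  # residue 2 has no side chain beyond O, so no chi2 label anywhere
  expect_false(any(grepl("^chi", colnames(te$samples)) &
                     grepl("_2$", colnames(te$samples))))
})

test_that("write_pdb round-trips coordinates and places B-factor scalars", {
  m <- helix_model(5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, f, bfactor = c(1.1, 2.2, 3.3, 4.4, 5.5))
  back <- read_pdb(f)
  expect_equal(n_residues(back), 5)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(m$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  b_by_res <- tapply(back$atoms$b, back$atoms$resno, unique)
  expect_equal(as.numeric(b_by_res), c(1.1, 2.2, 3.3, 4.4, 5.5))
})
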