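# Histogram entropy / mutual-information estimators and per-residue
# partial entropies

test_that("build_adjacency enumerates covalent pairs with correct ownership", {
  # ala-ala: torsions {psi_1, phi_2} -> single cross pair owned by residue 2
  te <- torsion_ensemble(matrix(0, 2, 2,
                                dimnames = list(NULL, c("psi_1", "phi_2"))),
                         sequence = "AA")
  adj <- build_adjacency(te)
  expect_equal(nrow(adj), 1)
  expect_equal(sort(c(adj$a, adj$b)), c("phi_2", "psi_1"))
  expect_equal(adj$owner, 2)

  # single residue: no pairs
  one <- torsion_ensemble(matrix(0, 2, 1, dimnames = list(NULL, "psi_1")),
                          sequence = "A")
  expect_equal(nrow(build_adjacency(one)), 0)

  # lysine at position 2: chi chain pairs all owned by residue 2
  cols <- c("psi_1", "phi_2", "psi_2", "chi1_2", "chi2_2", "chi3_2",
            "chi4_2", "phi_3")
  tk <- torsion_ensemble(matrix(0, 2, length(cols),
                                dimnames = list(NULL, cols)),
                         sequence = "AKA")
  adj <- build_adjacency(tk)
  key <- paste(adj$a, adj$b)
  expect_true(all(c("chi1_2 chi2_2", "chi2_2 chi3_2", "chi3_2 chi4_2")
                  %in% key))
  expect_true(all(adj$owner[grepl("chi", key)] == 2))
  expect_true(all(c("phi_2 psi_2", "phi_2 chi1_2", "psi_2 chi1_2") %in% key))
  # cross pairs owned by the downstream residue
  expect_equal(adj$owner[key == "psi_1 phi_2"], 2)
  expect_equal(adj$owner[key == "psi_2 phi_3"], 3)
  # every pair has exactly one owner and references existing labels
  expect_true(all(c(adj$a, adj$b) %in% cols))
  expect_false(anyDuplicated(key) > 0)
})

test_that("marginal_entropy recovers closed forms", {
  set.seed(1)
  u <- runif(1e5, -pi, pi)
  expect_equal(marginal_entropy(u), log(2 * pi), tolerance = 0.01)

  vm <- sample_torsion_ensemble(list(x_1 = list(type = "vonmises", mu = 0.5,
                                                kappa = 2)),
                                frames = 1e5, seed = 2)
  expect_equal(marginal_entropy(vm$ensemble$samples[, 1]),
               vonmises_entropy(2), tolerance = 0.02)
  expect_equal(vonmises_entropy(2), 1.2664, tolerance = 1e-4)

  # degenerate: one occupied bin gives exactly the single-bin floor
  expect_equal(marginal_entropy(rep(0.3, 500)), log(2 * pi / 30))
  expect_error(marginal_entropy(numeric(0)), "empty")
  expect_warning(marginal_entropy(runif(10, -pi, pi)), "fewer samples")
})

test_that("mutual_information behaves at independence, identity and coupling", {
  set.seed(5)
  x <- runif(1e5, -pi, pi); y <- runif(1e5, -pi, pi)
  expect_lte(mutual_information(x, y), 0.01)
  # copy case: I(x, x) equals the discrete marginal entropy (maximal)
  Ixx <- mutual_information(x, x, correction = "none")
  hx_disc <- marginal_entropy(x, correction = "none") - log(2 * pi / 30)
  expect_equal(Ixx, hx_disc, tolerance = 1e-10)

  cp <- sample_torsion_ensemble(
    list(a_1 = list(type = "uniform"), b_2 = list(type = "uniform")),
    frames = 1e5,
    coupled = data.frame(a = "a_1", b = "b_2", rho = 0.5), seed = 3
  )
  expect_lt(abs(mutual_information(cp$ensemble$samples[, 1],
                                   cp$ensemble$samples[, 2]) -
                  copula_mi(0.5)), 0.02)
  expect_equal(copula_mi(0.5), 0.1438, tolerance = 1e-3)
  expect_error(mutual_information(1:5, 1:4), "length mismatch")
})

test_that("partial entropies match the independence and rigid limits", {
  labs <- c("psi_1", "phi_2", "psi_2", "phi_3")
  marg <- stats::setNames(rep(list(list(type = "uniform")), 4), labs)
  s <- sample_torsion_ensemble(marg, frames = 2e4, seed = 9,
                               sequence = "AAA")
  prof <- partial_entropies(s$ensemble)
  expect_s3_class(prof, "entropy_profile")
  expect_equal(prof$total, sum(prof$Si), tolerance = 1e-12)
  expect_equal(prof$total, 4 * log(2 * pi), tolerance = 0.05)
  # residue 2 owns psi_1:phi_2 and phi_2:psi_2; residue 1 only psi_1
  expect_equal(unname(prof$Si[1]), log(2 * pi), tolerance = 0.02)

  # rigid ensemble: every torsion at the single-bin floor, all MI zero
  rigid <- torsion_ensemble(matrix(0.7, 5, 4, dimnames = list(NULL, labs)),
                            sequence = "AAA")
  pr <- suppressWarnings(partial_entropies(rigid))
  expect_equal(pr$total, 4 * log(2 * pi / 30), tolerance = 1e-10)
})

test_that("a planted intra-residue coupling lowers that residue's entropy", {
  labs <- c("psi_4", "phi_5", "psi_5", "phi_6")
  marg <- stats::setNames(rep(list(list(type = "uniform")), 4), labs)
  ind <- sample_torsion_ensemble(marg, frames = 5e4, seed = 13,
                                 sequence = strrep("A", 6))
  cpl <- sample_torsion_ensemble(marg, frames = 5e4,
                                 coupled = data.frame(a = "phi_5",
                                                      b = "psi_5",
                                                      rho = 0.8),
                                 seed = 13, sequence = strrep("A", 6))
  p_ind <- suppressWarnings(partial_entropies(ind$ensemble))
  p_cpl <- suppressWarnings(partial_entropies(cpl$ensemble))
  drop5 <- unname(p_ind$Si[5] - p_cpl$Si[5])
  expect_lt(abs(drop5 - copula_mi(0.8)), 0.04)
  expect_equal(copula_mi(0.8), 0.5108, tolerance = 1e-4)
  # other residues essentially unchanged
  expect_lt(abs(p_ind$Si[4] - p_cpl$Si[4]), 0.03)
})

test_that("total entropy is invariant under frame permutation and MIST-bounded", {
  labs <- c("psi_1", "phi_2", "psi_2", "phi_3")
  marg <- stats::setNames(rep(list(list(type = "uniform")), 4), labs)
  s <- sample_torsion_ensemble(marg, frames = 3000,
                               coupled = data.frame(a = "phi_2", b = "psi_2",
                                                    rho = 0.6),
                               seed = 4, sequence = "AAA")
  ens <- s$ensemble
  set.seed(8)
  shuf <- ens
  shuf$samples <- ens$samples[sample(nrow(ens$samples)), ]
  expect_equal(partial_entropies(shuf)$total, partial_entropies(ens)$total,
               tolerance = 1e-12)
  # subtracting clipped-nonnegative MI can only lower the total
  marg_sum <- sum(apply(ens$samples, 2, marginal_entropy))
  expect_lte(partial_entropies(ens)$total, marg_sum + 1e-12)
})

test_that("estimates tighten toward the analytic value as frames double", {
  marg <- list(x_1 = list(type = "vonmises", mu = 0, kappa = 2))
  errs <- vapply(c(1e3, 1e4, 1e5), function(F) {
    s <- sample_torsion_ensemble(marg, frames = F, seed = 17)
    abs(marginal_entropy(s$ensemble$samples[, 1]) - vonmises_entropy(2))
  }, numeric(1))
  expect_lt(errs[3], errs[1] + 0.005)
  expect_lt(errs[3], 0.02)
})

test_that("entropy differences cancel the unknown constant and sum by segment", {
  A <- fake_profile(c(rep(0.2, 52), rep(6.4 / 20 + 0.2, 20), rep(0.2, 8)))
  B <- fake_profile(rep(0.2, 80))
  expect_error(entropy_difference(A, fake_profile(rep(0, 79))),
               "different sequences|length")
  d <- entropy_difference(A, B)
  expect_equal(d$total, sum(d$deltaSi), tolerance = 1e-12)
  expect_equal(d$total, A$total - B$total, tolerance = 1e-12)
  z <- entropy_difference(A, A)
  expect_true(all(z$deltaSi == 0))
  seg <- segment_sum(d, 53, 72)
  expect_equal(seg$sum, 6.4, tolerance = 1e-9)
  all_seg <- segment_sum(d, 1, 80)
  expect_equal(all_seg$fraction, 1)
  expect_error(segment_sum(d, 0, 5), "invalid")
})

test_that("entropy converts to -TS in kcal/mol with kB = 0.0019872", {
  expect_equal(entropy_to_free_energy(0), 0)
  expect_equal(entropy_to_free_energy(1), -0.59616)
  # a 14.6 kB difference at 300 K is worth about -8.70 kcal/mol
  expect_equal(entropy_to_free_energy(14.6), -8.70, tolerance = 0.05)
})
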