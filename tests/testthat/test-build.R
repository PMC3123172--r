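test_that("assigned dihedrals are reproduced by the builder within 0.1 degree", {
  conf <- build_conformation("AAAAA", rep(HELIX_STATE, 5), AL, ff = FF)
  md <- measure_dihedrals(conf)
  target_phi <- AL$states$phi[HELIX_STATE]
  target_psi <- AL$states$psi[HELIX_STATE]
  expect_equal(md$phi[2:5], rep(target_phi, 4), tolerance = 0.1)
  expect_equal(md$psi[1:4], rep(target_psi, 4), tolerance = 0.1)
  expect_true(is.na(md$phi[1]) && is.na(md$psi[5]))
})

test_that("a single-residue glycine builds a valid degenerate conformation", {
  conf <- build_conformation("G", 1L, AL, ff = FF)
  expect_s3_class(conf, "conformation")
  expect_setequal(conf$atoms$name, c("N", "H", "CA", "C", "O"))
  md <- measure_dihedrals(conf)
  expect_true(is.na(md$phi) && is.na(md$psi))
})

test_that("trans-peptide CA-CA virtual bond is ~3.8 A in the extended state", {
  conf <- build_conformation("LL", rep(EXT_STATE, 2), AL, ff = FF)
  ca <- which(conf$atoms$name == "CA")
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")])
  expect_equal(sqrt(sum((xyz[ca[1], ] - xyz[ca[2], ])^2)), 3.8,
               tolerance = 0.05)
})

test_that("input validation names the offence", {
  expect_error(build_conformation("AXB", rep(1L, 3), AL, ff = FF),
               "unknown residue")
  expect_error(build_conformation("AAA", rep(1L, 2), AL, ff = FF),
               "length")
})

test_that("build-measure-rebuild round-trips to numerically identical atoms", {
  withr::with_seed(7, states <- sample.int(64, 12, replace = TRUE))
  conf <- build_conformation(strrep("A", 12), states, AL, ff = FF)
  md <- measure_dihedrals(conf)
  # psi of the last residue is only visible through its carbonyl:
  # dihedral(N, CA, C, O) = psi + 180
  ii <- function(r, nm) which(conf$atoms$resid == r & conf$atoms$name == nm)
  quad <- matrix(c(ii(12, "N"), ii(12, "CA"), ii(12, "C"), ii(12, "O")), 1)
  psi_last <- tmdscan:::cpp_measure_dihedrals(
    tmdscan:::coords_matrix(conf), quad) - 180
  phi <- c(0, md$phi[-1])
  psi <- c(md$psi[-12], psi_last)
  al2 <- make_alphabet(((phi + 180) %% 360) - 180, ((psi + 180) %% 360) - 180)
  conf2 <- build_conformation(strrep("A", 12), seq_len(12), al2, ff = FF)
  expect_lt(superposed_rmsd(conf, conf2), 1e-6)
})

test_that("hydrogen policy controls the amide hydrogens", {
  with_h <- build_conformation("GAP", rep(HELIX_STATE, 3), AL, ff = FF)
  no_h <- build_conformation("GAP", rep(HELIX_STATE, 3), AL,
                             hydrogen_policy = "none", ff = FF)
  # proline never carries an amide H
  expect_equal(sum(with_h$atoms$name == "H"), 2L)
  expect_equal(sum(no_h$atoms$name == "H"), 0L)
  expect_equal(nrow(with_h$atoms) - nrow(no_h$atoms), 2L)
})

test_that("all twenty residue types build clash-free ideal helices", {
  for (aa in names(tmdscan:::AA1)) {
    if (aa == "P") next  # proline is a genuine helix breaker
    conf <- helix_conf(paste0("GG", strrep(aa, 3), "GG"))
    expect_gt(min_heavy_distance(conf), 1.8)
  }
})

test_that("energies and surface areas are invariant under rigid motion", {
  conf <- helix_conf("LKAYV")
  rot <- random_rotation_matrix(11)
  moved <- tmdscan:::transform_conformation(conf, rot, c(13.2, -8, 4.4))
  for (term in c(lennard_jones_energy, coulomb_energy,
                 intramolecular_hydrophobicity_energy))
    expect_equal(term(conf, FF), term(moved, FF), tolerance = 1e-6)
  # the deterministic sphere point set is direction-fixed, so the sampled
  # surface is exactly invariant under translation (rotation re-quantizes)
  shifted <- tmdscan:::transform_conformation(conf, diag(3), c(5, -3, 11))
  a1 <- shrake_rupley_asa(conf, ff = FF)$atom$asa
  a2 <- shrake_rupley_asa(shifted, ff = FF)$atom$asa
  expect_equal(a1, a2, tolerance = 1e-9)
  e1 <- total_energy(conf, "hydrophilic", FF)
  e2 <- total_energy(shifted, "hydrophilic", FF)
  expect_equal(e1$e_total, e2$e_total, tolerance = 1e-6)
})
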