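test_that("an isolated sphere recovers its full accessible area", {
  one <- conformation_from_atoms(data.frame(x = 0, y = 0, z = 0, type = 1L),
                                 ff = FF)
  asa <- shrake_rupley_asa(one, ff = FF)$atom$asa
  r <- FF$types$r0[1] + FF$probe_radius
  expect_equal(asa, 4 * pi * r^2, tolerance = 0.02 * 4 * pi * r^2)
  expect_error(shrake_rupley_asa(one, n_points = 100), "162")
})

test_that("a tightly caged atom has zero accessible surface", {
  # central atom surrounded by an octahedron + cube of large neighbours
  d <- 2.2
  shell <- rbind(expand.grid(x = c(-d, d), y = c(-d, d), z = c(-d, d)),
                 data.frame(x = c(d, -d, 0, 0, 0, 0) * 1.45,
                            y = c(0, 0, d, -d, 0, 0) * 1.45,
                            z = c(0, 0, 0, 0, d, -d) * 1.45))
  atoms <- rbind(data.frame(x = 0, y = 0, z = 0), shell)
  atoms$type <- 1L
  caged <- conformation_from_atoms(atoms, ff = FF)
  asa <- shrake_rupley_asa(caged, ff = FF)$atom$asa
  expect_equal(asa[1], 0)
})

test_that("two overlapping spheres match the analytic cap solution", {
  r1 <- FF$types$r0[1] + FF$probe_radius
  d <- 2.5
  two <- conformation_from_atoms(
    data.frame(x = c(0, d), y = 0, z = 0, type = 1L), ff = FF)
  asa <- shrake_rupley_asa(two, ff = FF)$atom$asa
  # equal spheres: removed cap height h = r - d/2 on each
  h <- r1 - d / 2
  analytic <- 4 * pi * r1^2 - 2 * pi * r1 * h
  expect_equal(asa[1], analytic, tolerance = 0.03 * analytic)
  expect_equal(asa[2], analytic, tolerance = 0.03 * analytic)
})

test_that("the surface ratio is plain arithmetic with a capped denominator", {
  expect_equal(tmdscan:::asar_ratio(50, 10), 5)
  expect_equal(tmdscan:::asar_ratio(0, 30), 0)
  expect_equal(tmdscan:::asar_ratio(50, 0.01), 99.9)
  # leucine exposes more hydrophobic relative surface than aspartate
  conf <- helix_conf("GGLGGGDGG")
  ra <- residue_asar(shrake_rupley_asa(conf, ff = FF))
  expect_gt(ra$asar[3], ra$asar[7])
})

test_that("secondary structure needs both the dihedral circle and the H-bond", {
  hel <- helix_conf(strrep("A", 12))
  lab <- pex_assign(hel)$label
  expect_true(all(lab[3:10] == "alpha_helix"))
  expect_equal(lab[1], "coil")   # terminal residues lack a dihedral
  expect_equal(lab[12], "coil")
  ext <- build_conformation(strrep("A", 8), rep(EXT_STATE, 8), AL, ff = FF)
  lab_ext <- pex_assign(ext)$label
  expect_true(all(lab_ext[2:7] == "beta"))
  # a flipped residue loses its helix label through the dihedral test
  states <- rep(HELIX_STATE, 12)
  states[6] <- EXT_STATE
  broken <- build_conformation(strrep("A", 12), states, AL, ff = FF)
  lab_b <- pex_assign(broken)$label
  expect_false(lab_b[6] %in% c("alpha_helix", "three_ten_helix"))
  # helical dihedrals with every hydrogen bond broken (uniform expansion
  # keeps all dihedral angles but stretches H...O beyond 3 A): the
  # dihedral test alone is insufficient
  stretched <- tmdscan:::set_coords(hel, tmdscan:::coords_matrix(hel) * 1.5)
  lab_s <- pex_assign(stretched)$label
  expect_true(all(lab_s %in% c("coil", "beta")))
  noh <- build_conformation("AAAA", rep(HELIX_STATE, 4), AL,
                            hydrogen_policy = "none", ff = FF)
  expect_error(pex_assign(noh), "hydrogen")
})

test_that("a 19-mer ideal helix is at least 75% helical", {
  conf <- generate_fixture("ideal_alpha_coords", alphabet = AL, ff = FF)
  lab <- pex_assign(conf)$label
  expect_gte(tmdscan:::helical_fraction(lab), 75)
})

test_that("superposition RMSD removes rigid motion and matches bio3d", {
  a <- helix_conf("LKAYVDE")
  rot <- random_rotation_matrix(3)
  b <- tmdscan:::transform_conformation(a, rot, c(-4, 9, 2))
  expect_equal(superposed_rmsd(a, a), 0)
  expect_lt(superposed_rmsd(a, b), 1e-6)
  # independent oracle on genuinely different structures
  skip_if_not_installed("bio3d")
  c2 <- build_conformation("LKAYVDE",
                           c(rep(HELIX_STATE, 4), rep(EXT_STATE, 3)),
                           AL, ff = FF)
  xa <- as.vector(t(tmdscan:::coords_matrix(a)))
  xc <- as.vector(t(tmdscan:::coords_matrix(c2)))
  ref <- bio3d::rmsd(xa, xc, fit = TRUE)
  expect_equal(superposed_rmsd(a, c2), ref, tolerance = 1e-3)
  short <- helix_conf("LK")
  expect_error(superposed_rmsd(a, short), "atom counts")
})

test_that("pulling a structure apart increases its total accessible area", {
  conf <- helix_conf("LKAYV")
  xyz <- tmdscan:::coords_matrix(conf)
  apart <- tmdscan:::set_coords(conf, xyz * 3)
  expect_lt(sum(shrake_rupley_asa(conf, ff = FF)$atom$asa),
            sum(shrake_rupley_asa(apart, ff = FF)$atom$asa))
})
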