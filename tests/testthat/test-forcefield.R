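test_that("the dielectric rises sigmoidally from 1 to 80 between 0.2 and 1 nm", {
  expect_equal(sigmoid_dielectric(0.1, FF), 1)
  expect_equal(sigmoid_dielectric(1.5, FF), 80)
  expect_equal(sigmoid_dielectric(0.6, FF), 40.5)
  d <- seq(0, 2, by = 0.01)
  eps <- sigmoid_dielectric(d, FF)
  expect_true(all(diff(eps) >= 0))
  expect_lt(max(abs(eps[d <= 0.2] - 1)), 0.1)
  expect_lt(max(abs(eps[d >= 1] - 80)), 0.1)
  expect_error(sigmoid_dielectric(-0.1, FF), "negative")
})

test_that("the Lennard-Jones minimum sits at (2A/B)^(1/6) with depth -B^2/(4A)", {
  eps <- FF$types$eps[1]; rmin <- 2 * FF$types$r0[1]
  A <- eps * rmin^12; B <- 2 * eps * rmin^6
  dmin <- (2 * A / B)^(1 / 6)
  expect_equal(dmin, rmin)
  expect_equal(lj_pair(dmin, A, B), -B^2 / (4 * A))
  two <- conformation_from_atoms(
    data.frame(x = c(0, dmin), y = 0, z = 0, type = 1L), ff = FF)
  expect_equal(lennard_jones_energy(two, FF), -eps, tolerance = 1e-9)
})

test_that("1-2 and 1-3 bonded pairs are excluded, 1-4 kept at full weight", {
  # a bonded pair contributes nothing
  two <- conformation_from_atoms(
    data.frame(x = c(0, 1.5), y = 0, z = 0, type = 1L),
    bonds = cbind(1L, 2L), ff = FF)
  expect_equal(lennard_jones_energy(two, FF), 0)
  # a single glycine (N, CA, C, O) keeps exactly its N...O 1-4 pair
  conf <- build_conformation("G", 1L, AL, hydrogen_policy = "none", ff = FF)
  pp <- tmdscan:::nonbonded_pairs(nrow(conf$atoms), conf$bonds)
  expect_equal(nrow(pp), 1L)
  expect_setequal(conf$atoms$name[pp[1, ]], c("N", "O"))
})

test_that("conformation-level sums match a naive double-loop oracle", {
  withr::with_seed(4, {
    n <- 30
    atoms <- data.frame(x = runif(n, 0, 12), y = runif(n, 0, 12),
                        z = runif(n, 0, 12),
                        type = sample.int(7, n, replace = TRUE),
                        q = sample(c(0, 0.3, -0.3), n, replace = TRUE))
  })
  conf <- conformation_from_atoms(atoms, ff = FF)
  # oracle: plain R loops over all unordered pairs through the exported
  # pair primitives
  tt <- FF$types
  vdw <- coul <- pho <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((unlist(atoms[i, 1:3]) - unlist(atoms[j, 1:3]))^2))
    eps <- sqrt(tt$eps[atoms$type[i]] * tt$eps[atoms$type[j]])
    rmin <- tt$r0[atoms$type[i]] + tt$r0[atoms$type[j]]
    vdw <- vdw + lj_pair(d, eps * rmin^12, 2 * eps * rmin^6)
    coul <- coul + coulomb_pair(d, atoms$q[i], atoms$q[j], FF)
    pho <- pho + pho_pair(d, tt$etr[atoms$type[i]], tt$etr[atoms$type[j]],
                          tt$hydrophobic[atoms$type[i]],
                          tt$hydrophobic[atoms$type[j]],
                          tt$r0[atoms$type[i]], tt$r0[atoms$type[j]],
                          FF$rsol)
  }
  expect_equal(lennard_jones_energy(conf, FF), vdw, tolerance = 1e-9)
  expect_equal(coulomb_energy(conf, FF), coul, tolerance = 1e-9)
  expect_equal(intramolecular_hydrophobicity_energy(conf, FF), pho,
               tolerance = 1e-9)
})

test_that("Coulomb energy vanishes with null charges and is symmetric in them", {
  conf <- helix_conf("AAAA")
  conf$atoms$q <- 0
  expect_equal(coulomb_energy(conf, FF), 0)
  expect_equal(coulomb_pair(3, 0.5, -0.5, FF), coulomb_pair(3, -0.5, 0.5, FF))
  # single-pair closed form at 0.3 nm
  expect_equal(coulomb_pair(3, 0.5, -0.5, FF),
               FF$coulomb_k * -0.25 / (sigmoid_dielectric(0.3, FF) * 3))
})

test_that("hydrophobicity pair term decays and carries the delta sign rule", {
  # contact vs far separation
  e_near <- pho_pair(3.4, 0.08, 0.08, TRUE, TRUE, 1.7, 1.7, 1.4)
  e_far <- pho_pair(20, 0.08, 0.08, TRUE, TRUE, 1.7, 1.7, 1.4)
  expect_gt(abs(e_near), 100 * abs(e_far))
  # like pairs attract (negative), mixed pairs repel (positive)
  e_hh <- pho_pair(3.4, 0.08, 0.08, TRUE, TRUE, 1.7, 1.7, 1.4)
  e_pp <- pho_pair(3.1, 0.06, 0.06, FALSE, FALSE, 1.55, 1.55, 1.4)
  e_mix <- pho_pair(3.3, 0.08, 0.06, TRUE, FALSE, 1.7, 1.55, 1.4)
  expect_lt(e_hh, 0); expect_lt(e_pp, 0); expect_gt(e_mix, 0)
  # frozen single-term evaluation: two hydrophobic atoms, Etr 1 per A^2,
  # r0 1.7, at hard contact d = 3.4, rsol 1.4: coverage of the solvent-
  # augmented spheres (R = 3.1) at 3.4 A is f = h/(2R) with
  # h = R - d/2 = 1.4, the exponential factor is 1, and the per-atom
  # transfer energy is 4*pi*R^2
  f <- (3.1 - 3.4 / 2) / (2 * 3.1)
  expected <- -1 * (4 * pi * 3.1^2) * f * 1
  expect_equal(pho_pair(3.4, 1, 1, TRUE, TRUE, 1.7, 1.7, 1.4), expected,
               tolerance = 1e-12)
})

test_that("solvation energy is the transfer-weighted exposed surface", {
  conf <- helix_conf("AKA")
  asa <- rep(0, nrow(conf$atoms))
  expect_equal(solvation_energy(conf, FF, asa = asa), 0)
  asa1 <- shrake_rupley_asa(conf, ff = FF)$atom$asa
  e1 <- solvation_energy(conf, FF, asa = asa1)
  expect_equal(solvation_energy(conf, FF, asa = 2 * asa1), 2 * e1)
  # 3-atom hand sum
  toy <- conformation_from_atoms(
    data.frame(x = c(0, 9, 18), y = 0, z = 0, type = 1L), ff = FF)
  toy$atoms$etr <- c(1, -2, 0.5)
  expect_equal(solvation_energy(toy, FF, asa = c(10, 5, 0)), 0)
  expect_error(solvation_energy(conf, FF, asa = asa1[-1]), "length")
})

test_that("total energy is environment bookkeeping over its components", {
  conf <- helix_conf("LKAYV")
  ephil <- total_energy(conf, "hydrophilic", FF)
  ephob <- total_energy(conf, "hydrophobic", FF)
  expect_equal(ephil$e_total,
               ephil$e_vdw + ephil$e_coulomb + ephil$e_pho_intra +
                 ephil$e_solvation, tolerance = 1e-9)
  expect_equal(ephob$e_total,
               ephob$e_vdw + ephob$e_coulomb + ephob$e_pho_intra +
                 ephob$e_apolar_transfer, tolerance = 1e-9)
  # the transfer term flips sign between the two media
  expect_equal(ephil$e_solvation, -ephob$e_apolar_transfer, tolerance = 1e-9)
  expect_equal(ephil$e_total - ephob$e_total,
               2 * solvation_energy(conf, FF), tolerance = 1e-6)
  expect_error(total_energy(conf, "vacuum", FF))
})
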