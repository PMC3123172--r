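test_that("the interface function honors its plateaus and symmetry", {
  expect_equal(interface_function(0, MB), 0, tolerance = 1e-3)
  expect_equal(interface_function(2.5, MB), 1, tolerance = 1e-3)
  expect_equal(interface_function(1.35, MB), 1e-3, tolerance = 1e-5)
  expect_equal(interface_function(1.8, MB), 1 - 1e-3, tolerance = 1e-5)
  for (z in c(0.5, 1.5, 2.0))
    expect_equal(interface_function(z, MB), interface_function(-z, MB))
  z <- seq(-3, 3, by = 0.01)
  cz <- interface_function(z, MB)
  expect_true(all(cz >= 0 & cz <= 1))
  expect_lt(max(abs(cz[abs(z) < 1.35])), 1e-3)
  expect_lt(max(abs(1 - cz[abs(z) > 1.8])), 1e-3)
})

test_that("membrane energy terms obey their plateau arithmetic", {
  conf <- generate_fixture("poly_leu_helix", alphabet = AL, ff = FF)
  asa <- shrake_rupley_asa(conf, ff = FF)$atom$asa
  # fully aqueous: both terms vanish
  far <- tmdscan:::transform_conformation(conf, diag(3), c(0, 0, 60))
  expect_equal(membrane_hydrophobicity_energy(far, MB, asa, FF), 0,
               tolerance = 1e-4)
  expect_equal(lipid_perturbation_energy(far, MB, asa, FF), 0,
               tolerance = 1e-4)
  # buried flat at the bilayer center: E_lip = alip * total surface and
  # the transfer term equals the negated apolar transfer budget
  ca <- which(conf$atoms$name == "CA")
  xyz <- tmdscan:::coords_matrix(conf)
  axis <- xyz[ca[19], ] - xyz[ca[1], ]
  axis <- axis / sqrt(sum(axis^2))
  # rotate the helix axis into the membrane plane (x axis)
  v <- c(1, 0, 0)
  # build rotation sending axis -> x via Rodrigues
  k <- c(axis[2] * v[3] - axis[3] * v[2],
         axis[3] * v[1] - axis[1] * v[3],
         axis[1] * v[2] - axis[2] * v[1])
  s <- sqrt(sum(k^2)); cth <- sum(axis * v)
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3,
              byrow = TRUE)
  R <- diag(3) + K + K %*% K * ((1 - cth) / s^2)
  flat <- tmdscan:::transform_conformation(conf, R)
  cen <- colMeans(tmdscan:::coords_matrix(flat))
  flat <- tmdscan:::transform_conformation(flat, diag(3), -cen)
  expect_equal(lipid_perturbation_energy(flat, MB, asa, FF),
               MB$alip * sum(asa), tolerance = 0.01)
  expect_equal(membrane_hydrophobicity_energy(flat, MB, asa, FF),
               -sum(flat$atoms$etr * asa), tolerance = 0.05)
  # linearity in the surface
  expect_equal(lipid_perturbation_energy(flat, MB, asa / 2, FF),
               lipid_perturbation_energy(flat, MB, asa, FF) / 2)
})

test_that("insertion scans are deterministic and never beat a denser oracle", {
  conf <- generate_fixture("poly_leu_helix", alphabet = AL, ff = FF)
  r1 <- insertion_scan(conf, MB, seed = 5, ff = FF, n_trials = 200)
  r2 <- insertion_scan(conf, MB, seed = 5, ff = FF, n_trials = 200)
  expect_identical(r1$profile, r2$profile)
  expect_identical(r1$best_z, r2$best_z)
  expect_equal(r1$e_pot_mem, min(r1$profile$energy))
  expect_true(r1$tilt_deg >= 0 && r1$tilt_deg <= 90)
  # the coarse random scan may only miss minima, never invent them
  dense <- insertion_scan(conf, MB, ff = FF, mode = "grid",
                          tilt_step = 5, spin_step = 10)
  coarse <- insertion_scan(conf, MB, seed = 9, ff = FF, n_trials = 50)
  expect_gte(coarse$e_pot_mem, dense$e_pot_mem - 1e-6)
})

test_that("a 180-degree in-plane flip leaves the best energy unchanged", {
  conf <- generate_fixture("poly_leu_helix", alphabet = AL, ff = FF)
  flip <- tmdscan:::transform_conformation(
    conf, matrix(c(1, 0, 0, 0, -1, 0, 0, 0, -1), 3, byrow = TRUE))
  a <- insertion_scan(conf, MB, ff = FF, mode = "grid",
                      tilt_step = 10, spin_step = 20)
  b <- insertion_scan(flip, MB, ff = FF, mode = "grid",
                      tilt_step = 10, spin_step = 20)
  expect_equal(a$e_pot_mem, b$e_pot_mem, tolerance = 0.05 * abs(a$e_pot_mem))
})

test_that("a hydrophobic helix buries at the bilayer center, a charged one will not", {
  leu <- generate_fixture("poly_leu_helix", alphabet = AL, ff = FF)
  lys <- generate_fixture("poly_lys_helix", alphabet = AL, ff = FF)
  rl <- insertion_scan(leu, MB, seed = 1, ff = FF, n_trials = 500)
  rk <- insertion_scan(lys, MB, seed = 1, ff = FF, n_trials = 500)
  expect_lte(abs(rl$best_z), 3)
  expect_lt(rl$e_pot_mem, rk$e_pot_mem)
  expect_lt(rl$e_pot_mem, 0)
})

test_that("empty conformations are rejected", {
  empty <- conformation_from_atoms(
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0)), ff = FF)
  expect_error(insertion_scan(empty, MB, ff = FF), "empty")
})
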