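# Implicit DPPC bilayer: interface function, membrane energy terms and the
# z/orientation insertion scan.

#' Implicit-bilayer model
#'
#' The bilayer is described by a water-phase interface function
#' \eqn{C(z) = 1/(1 + e^{\alpha (z_0 - |z|)})}, symmetric about the bilayer
#' center z = 0 (membrane normal along z), with \eqn{z_0} and
#' \eqn{\alpha} fitted so that C = tol at the core half-width (1.35 nm)
#' and 1 - tol at the water bound (1.8 nm), tol = 1e-3: C is 0 throughout
#' the acyl core and 1 in water.
#'
#' @param ff Force field (membrane block of the parameter file).
#' @param z_step Scan step along z, Angstrom.
#' @param z_range Scan range for the peptide centroid, `c(zmin, zmax)` in
#'   Angstrom (the default +-10 A keeps a 19-mer centroid in the core).
#' @param n_trials Random orientations per z position.
#' @param alip Lipid-perturbation constant.
#' @return A `membrane_model` list: `z0`, `alpha` (Angstrom units), scan
#'   defaults and `alip`.
#' @export
membrane_model <- function(ff = load_forcefield(), z_step = 0.1,
                           z_range = c(-10, 10), n_trials = 10000L,
                           alip = NULL) {
  mb <- ff$membrane
  tol <- mb$plateau_tolerance
  zc <- mb$core_half_width_nm * 10     # Angstrom
  zw <- mb$water_bound_nm * 10
  # logistic through C(zc) = tol, C(zw) = 1 - tol
  alpha <- 2 * log((1 - tol) / tol) / (zw - zc)
  z0 <- (zc + zw) / 2
  structure(list(z0 = z0, alpha = alpha,
                 core_half_width_nm = mb$core_half_width_nm,
                 water_bound_nm = mb$water_bound_nm,
                 alip = if (is.null(alip)) mb$alip else alip,
                 z_step = z_step, z_range = z_range,
                 n_trials = as.integer(n_trials)),
            class = "membrane_model")
}

#' @export
print.membrane_model <- function(x, ...) {
  cat(sprintf("<membrane_model> core |z| < %.2f nm, water |z| > %.2f nm, alip %.3f\n",
              x$core_half_width_nm, x$water_bound_nm, x$alip))
  invisible(x)
}

#' Bilayer interface function C(z)
#'
#' @param z_nm Position(s) along the membrane normal, nm (bilayer center
#'   at 0).
#' @param membrane A [membrane_model()].
#' @return Value(s) in \[0, 1\]: ~0 inside the acyl core (|z| < 1.35 nm),
#'   ~1 in water (|z| > 1.8 nm).
#' @export
interface_function <- function(z_nm, membrane = membrane_model()) {
  az <- abs(z_nm) * 10
  1 / (1 + exp(membrane$alpha * (membrane$z0 - az)))
}

# per-atom burial weights shared by the membrane energy terms
atom_burial <- function(x, membrane, asa) {
  if (length(asa) != nrow(x$atoms))
    stop("ASA vector length does not match the atom count", call. = FALSE)
  1 - interface_function(x$atoms$z / 10, membrane)
}

#' Membrane hydrophobicity (transfer) energy
#'
#' \eqn{E = -\sum_i Etr_i S_i (1 - C(z_i))}: the surface-weighted transfer
#' stabilization of atoms buried in the acyl core, relative to the fully
#' aqueous state (E = 0 in water).  With the package convention Etr > 0
#' for hydrophobic atoms, burying hydrophobic surface is favourable and
#' burying polar/charged surface is penalized; the buried-atom term equals
#' the negated water-to-membrane transfer free energy weighted by exposed
#' area.
#'
#' @param x A `conformation` placed in absolute membrane coordinates
#'   (z axis = membrane normal, bilayer center at z = 0).
#' @param membrane A [membrane_model()].
#' @param asa Per-atom accessible surface of the isolated peptide (A^2);
#'   computed if missing.
#' @param ff Force field.
#' @return Energy, kJ/mol.
#' @export
membrane_hydrophobicity_energy <- function(x, membrane = membrane_model(),
                                           asa = NULL, ff = load_forcefield()) {
  if (is.null(asa)) asa <- shrake_rupley_asa(x, ff = ff)$atom$asa
  -sum(x$atoms$etr * asa * atom_burial(x, membrane, asa))
}

#' Lipid-perturbation energy
#'
#' \eqn{E = a_{lip} \sum_i S_i (1 - C(z_i))}: every unit of peptide
#' surface inserted into the bilayer perturbs lipid packing at a constant
#' cost \eqn{a_{lip}} (0.018 by default); zero for a fully aqueous
#' peptide, never negative.
#'
#' @inheritParams membrane_hydrophobicity_energy
#' @return Energy, kJ/mol (non-negative).
#' @export
lipid_perturbation_energy <- function(x, membrane = membrane_model(),
                                      asa = NULL, ff = load_forcefield()) {
  if (is.null(asa)) asa <- shrake_rupley_asa(x, ff = ff)$atom$asa
  membrane$alip * sum(asa * atom_burial(x, membrane, asa))
}

#' Membrane potential energy at the current placement
#'
#' Sum of [membrane_hydrophobicity_energy()] and
#' [lipid_perturbation_energy()].
#'
#' @inheritParams membrane_hydrophobicity_energy
#' @return Energy, kJ/mol.
#' @export
membrane_potential_energy <- function(x, membrane = membrane_model(),
                                      asa = NULL, ff = load_forcefield()) {
  if (is.null(asa)) asa <- shrake_rupley_asa(x, ff = ff)$atom$asa
  membrane_hydrophobicity_energy(x, membrane, asa, ff) +
    lipid_perturbation_energy(x, membrane, asa, ff)
}

# uniform random rotation matrices (Shepperd quaternion method), using the
# R RNG so seeds propagate; returns K x 9 row-major matrices
random_rotations <- function(k) {
  u1 <- stats::runif(k); u2 <- stats::runif(k); u3 <- stats::runif(k)
  qw <- sqrt(1 - u1) * sin(2 * pi * u2)
  qx <- sqrt(1 - u1) * cos(2 * pi * u2)
  qy <- sqrt(u1) * sin(2 * pi * u3)
  qz <- sqrt(u1) * cos(2 * pi * u3)
  cbind(1 - 2 * (qy^2 + qz^2), 2 * (qx * qy - qz * qw), 2 * (qx * qz + qy * qw),
        2 * (qx * qy + qz * qw), 1 - 2 * (qx^2 + qz^2), 2 * (qy * qz - qx * qw),
        2 * (qx * qz - qy * qw), 2 * (qy * qz + qx * qw), 1 - 2 * (qx^2 + qy^2))
}

# deterministic tilt x spin grid (oracle mode)
grid_rotations <- function(tilt_step = 5, spin_step = 10) {
  tilts <- seq(0, 180, by = tilt_step) * pi / 180
  spins <- seq(0, 360 - spin_step, by = spin_step) * pi / 180
  out <- matrix(0, nrow = length(tilts) * length(spins), ncol = 9)
  k <- 0
  for (t in tilts) for (s in spins) {
    k <- k + 1
    ry <- matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)), 3, 3,
                 byrow = TRUE)
    rz <- matrix(c(cos(s), -sin(s), 0, sin(s), cos(s), 0, 0, 0, 1), 3, 3,
                 byrow = TRUE)
    out[k, ] <- as.vector(t(ry %*% rz))
  }
  out
}

#' Scan membrane insertion of a rigid peptide
#'
#' Moves the peptide centroid along the membrane normal with a constant
#' step (0.1 A by default) over the scan range; at each z position a set
#' of rigid-body orientations is tried (10000 uniform random rotations by
#' default, or a deterministic tilt/spin grid) and the lowest membrane
#' potential \eqn{E_{pho,mem} + E_{lip}} is recorded.  The global optimum
#' gives the best insertion depth and tilt.
#'
#' @param x A `conformation`.
#' @param membrane A [membrane_model()].
#' @param seed Integer seed for the random orientations (ignored in grid
#'   mode); the scan is deterministic given the seed.
#' @param ff Force field.
#' @param n_trials Orientations per scan (overrides the model default).
#' @param z_step,z_range Override the model scan grid (Angstrom).
#' @param mode `"random"` or `"grid"` (deterministic tilt/spin oracle).
#' @param tilt_step,spin_step Grid resolution in degrees (grid mode).
#' @param asa Optional precomputed per-atom ASA of the isolated peptide.
#' @return An `insertion_result`: `best_z` (A), `tilt_deg` in \[0, 90\],
#'   `e_pot_mem` (kJ/mol), and the per-z `profile` tibble.
#' @export
insertion_scan <- function(x, membrane = membrane_model(), seed = 1L,
                           ff = load_forcefield(), n_trials = NULL,
                           z_step = NULL, z_range = NULL,
                           mode = c("random", "grid"),
                           tilt_step = 5, spin_step = 10, asa = NULL) {
  mode <- match.arg(mode)
  if (nrow(x$atoms) == 0) stop("empty conformation", call. = FALSE)
  if (is.null(n_trials)) n_trials <- membrane$n_trials
  if (is.null(z_step)) z_step <- membrane$z_step
  if (is.null(z_range)) z_range <- membrane$z_range
  if (is.null(asa)) asa <- shrake_rupley_asa(x, ff = ff)$atom$asa
  u <- asa * (membrane$alip - x$atoms$etr)
  rots <- if (mode == "grid") grid_rotations(tilt_step, spin_step)
          else withr::with_seed(seed, random_rotations(n_trials))
  zgrid <- seq(z_range[1], z_range[2], by = z_step)
  res <- cpp_insertion_scan(coords_matrix(x), u, rots, zgrid,
                            membrane$z0, membrane$alpha)
  # helix axis = first-to-last CA direction; tilt vs membrane normal
  ca <- which(x$atoms$name == "CA")
  axis <- if (length(ca) >= 2) {
    xyz <- coords_matrix(x)
    v <- xyz[ca[length(ca)], ] - xyz[ca[1], ]
    v / sqrt(sum(v^2))
  } else c(0, 0, 1)
  rbest <- matrix(res$profile_rot, ncol = 1)
  tilt_of <- function(ridx) {
    m <- matrix(rots[ridx, ], 3, 3, byrow = TRUE)
    ct <- abs(sum(m[3, ] * axis))
    acos(pmin(1, ct)) * 180 / pi
  }
  structure(list(
    best_z = res$best_z,
    tilt_deg = tilt_of(res$best_rot),
    e_pot_mem = res$best_energy,
    profile = tibble::tibble(z = zgrid, energy = res$profile_energy,
                             tilt_deg = vapply(res$profile_rot, tilt_of,
                                               numeric(1))),
    n_trials = if (mode == "grid") nrow(rots) else n_trials,
    mode = mode, seed = seed),
    class = "insertion_result")
}

#' @export
print.insertion_result <- function(x, ...) {
  cat(sprintf("<insertion_result> best z %.2f A, tilt %.1f deg, E %.2f kJ/mol (%s, %d orientations)\n",
              x$best_z, x$tilt_deg, x$e_pot_mem, x$mode, x$n_trials))
  invisible(x)
}
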