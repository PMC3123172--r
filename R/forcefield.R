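# Non-bonded energy model: Lennard-Jones 6-12, Coulomb with a
# distance-dependent (smoothstep) dielectric, an intramolecular atomic
# hydrophobicity term, and implicit solvation as transfer energy times
# accessible surface.

#' Load non-bonded force-field parameters
#'
#' Reads the packaged (or a user-supplied) YAML parameter file: the
#' seven-type atomic classification with van der Waals radii/well depths,
#' transfer energies per unit accessible area, the water radius, dielectric
#' bounds and the implicit-membrane constants.  The packaged values are
#' documented stand-ins assembled from standard published parameters.
#'
#' @param path Path to a parameter file; default is the packaged set.
#' @return A `forcefield` object (list of parameter tables).
#' @export
load_forcefield <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "forcefield.yaml", package = "tmdscan")
  ff <- yaml::read_yaml(path)
  tt <- dplyr::bind_rows(lapply(ff$types, tibble::as_tibble))
  if (nrow(tt) != 7L || !identical(sort(tt$id), 1:7))
    stop("force-field file must define exactly the seven atomic types 1..7",
         call. = FALSE)
  tt <- tt[order(tt$id), ]
  ff$types <- tt
  # dielectric in Angstrom units for internal use
  ff$diel <- c(dlo = ff$dielectric$d_low_nm * 10,
               dhi = ff$dielectric$d_high_nm * 10,
               elo = ff$dielectric$eps_low, ehi = ff$dielectric$eps_high)
  class(ff) <- "forcefield"
  ff
}

#' @export
print.forcefield <- function(x, ...) {
  cat("<forcefield> version", x$version, "- 7 atomic types, rsol",
      x$rsol, "A, cutoff", x$cutoff, "A\n")
  invisible(x)
}

# ---- pair-level primitives (exact, vectorized) ----

#' Lennard-Jones 6-12 pair energy
#'
#' \eqn{E = A/d^{12} - B/d^6}.
#'
#' @param d Distance(s), Angstrom.
#' @param A,B Pair coefficients.
#' @return Energy, kJ/mol.
#' @export
lj_pair <- function(d, A, B) A / d^12 - B / d^6

#' Distance-dependent dielectric
#'
#' Sigmoidal (cubic smoothstep) rise of the dielectric constant from its
#' contact value to the bulk-water value across the stated transition
#' interval of interatomic separation (by default 1 to 80 between 0.2 and
#' 1 nm).
#'
#' @param distance_nm Interatomic distance(s) in nm.
#' @param ff A [load_forcefield()] object.
#' @return Dielectric constant(s), monotone non-decreasing in distance.
#' @export
sigmoid_dielectric <- function(distance_nm, ff = load_forcefield()) {
  if (any(distance_nm < 0)) stop("negative distance", call. = FALSE)
  dlo <- ff$dielectric$d_low_nm; dhi <- ff$dielectric$d_high_nm
  elo <- ff$dielectric$eps_low;  ehi <- ff$dielectric$eps_high
  t <- pmin(1, pmax(0, (distance_nm - dlo) / (dhi - dlo)))
  elo + (ehi - elo) * t^2 * (3 - 2 * t)
}

#' Coulomb pair energy with distance-dependent screening
#'
#' @param d Distance(s), Angstrom.
#' @param qi,qj Fractional charges (units of e).
#' @param ff Force field (for the electrostatic constant and dielectric).
#' @return Energy, kJ/mol.
#' @export
coulomb_pair <- function(d, qi, qj, ff = load_forcefield()) {
  ff$coulomb_k * qi * qj / (sigmoid_dielectric(d / 10, ff) * d)
}

#' Intramolecular hydrophobicity pair energy
#'
#' \eqn{E = \delta_{ij}\sqrt{|Etr_i\,Etr_j|}\,\tfrac{f_{ij}+f_{ji}}{2}\,
#' \exp\{-(d - r^0_i - r^0_j)/(2 r_{sol})\}} where \eqn{\delta_{ij}} is -1
#' for two hydrophobic or two hydrophilic atoms and +1 for a mixed pair,
#' and \eqn{f_{ij}} is the fraction of the solvent-augmented sphere of atom
#' i (radius \eqn{r^0_i + r_{sol}}) occluded by that of atom j (analytic
#' spherical-cap formula).  Both factors are clamped at hard-sphere contact
#' (\eqn{d < r^0_i + r^0_j}); the term vanishes once the augmented spheres
#' separate.
#'
#' @param d Distance(s), Angstrom.
#' @param etri,etrj Transfer energies per unit area (kJ/mol/A^2); each
#'   atom's total transfer energy is `etr * 4 pi (r0 + rsol)^2`, its
#'   isolated solvent-accessible sphere area.
#' @param phobi,phobj Logical hydrophobicity of the two atoms.
#' @param r0i,r0j van der Waals radii, Angstrom.
#' @param rsol Water radius, Angstrom.
#' @return Energy, kJ/mol.
#' @export
pho_pair <- function(d, etri, etrj, phobi, phobj, r0i, r0j, rsol = 1.4) {
  delta <- ifelse(phobi == phobj, -1, 1)
  Ri <- r0i + rsol; Rj <- r0j + rsol
  etot_i <- etri * 4 * pi * Ri^2
  etot_j <- etrj * 4 * pi * Rj^2
  dc <- pmax(d, r0i + r0j)
  f <- rep(0, length(dc))
  ok <- dc < Ri + Rj
  if (any(ok)) {
    hi <- Ri - (dc[ok]^2 + Ri^2 - Rj^2) / (2 * dc[ok])
    hj <- Rj - (dc[ok]^2 + Rj^2 - Ri^2) / (2 * dc[ok])
    fi <- pmin(1, pmax(0, hi / (2 * Ri)))
    fj <- pmin(1, pmax(0, hj / (2 * Rj)))
    f[ok] <- (fi + fj) / 2
  }
  delta * sqrt(abs(etot_i * etot_j)) * f * exp(-(dc - r0i - r0j) / (2 * rsol))
}

# ---- per-conformation machinery ----

# pair parameter table for a conformation (exact path); respects 1-2/1-3
# exclusions recorded in the conformation's bond graph
pair_params <- function(x, ff) {
  atoms <- x$atoms
  np <- nrow(atoms)
  pp <- if (!is.null(x$pairs)) x$pairs else
    nonbonded_pairs(np, if (is.null(x$bonds)) cbind(i = integer(0), j = integer(0)) else x$bonds)
  i <- pp[, 1]; j <- pp[, 2]
  tt <- ff$types
  ti <- atoms$type[i]; tj <- atoms$type[j]
  eps <- sqrt(tt$eps[ti] * tt$eps[tj])
  rmin <- tt$r0[ti] + tt$r0[tj]
  delta <- ifelse(tt$hydrophobic[ti] == tt$hydrophobic[tj], -1, 1)
  list(i = i, j = j,
       A = eps * rmin^12, B = 2 * eps * rmin^6,
       phomag = delta * sqrt(abs(tt$etr[ti] * 4 * pi * (tt$r0[ti] + ff$rsol)^2 *
                                 tt$etr[tj] * 4 * pi * (tt$r0[tj] + ff$rsol)^2)),
       r0i = tt$r0[ti], r0j = tt$r0[tj],
       qq = ff$coulomb_k * atoms$q[i] * atoms$q[j])
}

nonbonded_components <- function(x, ff) {
  stopifnot(inherits(x, "conformation"))
  pp <- pair_params(x, ff)
  if (!length(pp$i)) return(list(vdw = 0, coulomb = 0, pho = 0))
  cpp_energy_components(coords_matrix(x), pp$i, pp$j, pp$A, pp$B,
                        pp$phomag, pp$r0i, pp$r0j, pp$qq, ff$rsol,
                        unname(ff$diel))
}

#' Lennard-Jones energy of a conformation
#'
#' Sum of 6-12 pair terms over all non-bonded atom pairs (1-2 and 1-3
#' bonded pairs excluded, 1-4 and beyond at full weight), with pair
#' coefficients from the seven-type parameter table under Lorentz-Berthelot
#' combination (\eqn{A = \epsilon r_{min}^{12}}, \eqn{B = 2\epsilon
#' r_{min}^6}, \eqn{r_{min} = r^0_i + r^0_j}).
#'
#' @param x A [build_conformation()] or [conformation_from_atoms()] object.
#' @param ff Force field.
#' @return Energy, kJ/mol.
#' @export
lennard_jones_energy <- function(x, ff = load_forcefield())
  nonbonded_components(x, ff)$vdw

#' Coulomb energy of a conformation
#'
#' @inheritParams lennard_jones_energy
#' @return Energy, kJ/mol; zero when all partial charges are zero.
#' @export
coulomb_energy <- function(x, ff = load_forcefield())
  nonbonded_components(x, ff)$coulomb

#' Intramolecular hydrophobicity energy of a conformation
#'
#' @inheritParams lennard_jones_energy
#' @return Energy, kJ/mol (see [pho_pair()] for the pair form).
#' @export
intramolecular_hydrophobicity_energy <- function(x, ff = load_forcefield())
  nonbonded_components(x, ff)$pho

#' Implicit solvation energy
#'
#' \eqn{E = \sum_i Etr_i S_i}: exposing hydrophobic surface to water is
#' penalized, exposing hydrophilic surface favoured.
#'
#' @inheritParams lennard_jones_energy
#' @param asa Optional per-atom accessible surface areas (A^2); computed
#'   with [shrake_rupley_asa()] when missing.
#' @return Energy, kJ/mol.
#' @export
solvation_energy <- function(x, ff = load_forcefield(), asa = NULL) {
  if (is.null(asa)) asa <- shrake_rupley_asa(x, ff = ff)$atom$asa
  if (length(asa) != nrow(x$atoms))
    stop("ASA vector length does not match the atom count", call. = FALSE)
  sum(x$atoms$etr * asa)
}

#' Total energy with environment bookkeeping
#'
#' Hydrophilic environment: Lennard-Jones + Coulomb + intramolecular
#' hydrophobicity + implicit solvation (\eqn{+\sum Etr_i S_i}).
#' Hydrophobic (uniform apolar) environment: the transfer term changes
#' sign (\eqn{-\sum Etr_i S_i}): exposing polar surface to the apolar
#' medium costs energy, which is what drives backbone hydrogen bonding and
#' helix formation in a membrane-like medium.  Membrane environment: the
#' transfer term is replaced by the implicit-bilayer potential at the best
#' insertion found by [insertion_scan()].  (Inside the sampling engine the
#' hydrophobic-environment term uses a fast pairwise-occlusion surface
#' approximation; this function reports the exact Shrake-Rupley value.)
#'
#' @inheritParams lennard_jones_energy
#' @param environment One of `"hydrophilic"`, `"hydrophobic"`, `"membrane"`.
#' @param membrane Membrane model (membrane environment only).
#' @param insertion Optional precomputed [insertion_scan()] result.
#' @return A list of class `energy_breakdown` with components `e_vdw`,
#'   `e_coulomb`, `e_pho_intra`, `e_solvation` or `e_membrane`, `e_total`.
#' @export
total_energy <- function(x, environment = c("hydrophobic", "hydrophilic",
                                            "membrane"),
                         ff = load_forcefield(), membrane = NULL,
                         insertion = NULL) {
  environment <- match.arg(environment)
  nb <- nonbonded_components(x, ff)
  out <- list(e_vdw = nb$vdw, e_coulomb = nb$coulomb, e_pho_intra = nb$pho)
  if (environment == "hydrophilic") {
    out$e_solvation <- solvation_energy(x, ff)
  } else if (environment == "hydrophobic") {
    out$e_apolar_transfer <- -solvation_energy(x, ff)
  } else if (environment == "membrane") {
    if (is.null(insertion)) {
      if (is.null(membrane)) membrane <- membrane_model(ff)
      insertion <- insertion_scan(x, membrane, ff = ff, n_trials = 200,
                                  z_step = 0.5)
    }
    out$e_membrane <- insertion$e_pot_mem
  }
  out$e_total <- sum(unlist(out))
  out$environment <- environment
  class(out) <- "energy_breakdown"
  out
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("<energy_breakdown> [", x$environment, "]\n", sep = "")
  for (nm in setdiff(names(x), c("environment")))
    cat(sprintf("  %-12s %10.3f kJ/mol\n", nm, x[[nm]]))
  invisible(x)
}

# tabulated kernels per ordered type pair (7 x 7 = 49), indexed by squared
# distance; used by the compiled sampling engine.
type_pair_index <- function(ti, tj) {
  as.integer((ti - 1L) * 7L + tj)
}

# occlusion fraction of the solvent-accessible sphere of an atom of type a
# (radius r0a + rsol) by the accessible sphere of a type-b neighbour at
# distance d, clamped at hard contact (the approximate-burial kernel of the
# sampling engine; identical cap geometry to pho_pair)
occlusion_fraction <- function(d, r0a, r0b, rsol) {
  Ra <- r0a + rsol; Rb <- r0b + rsol
  dc <- pmax(d, r0a + r0b)
  f <- rep(0, length(dc))
  ok <- dc < Ra + Rb
  if (any(ok)) {
    h <- Ra - (dc[ok]^2 + Ra^2 - Rb^2) / (2 * dc[ok])
    f[ok] <- pmin(1, pmax(0, h / (2 * Ra)))
  }
  f
}

build_ftab <- function(ff, nbins = 1024L) {
  tt <- ff$types
  cut <- ff$cutoff
  d <- sqrt(seq(0, cut^2, length.out = nbins + 1L))
  d <- pmax(d, 0.8)  # clamp the wall; clashes are rejected upstream anyway
  ftab <- matrix(0, nrow = nbins + 1L, ncol = 49L)
  focc_i <- matrix(0, nrow = nbins + 1L, ncol = 49L)
  focc_j <- matrix(0, nrow = nbins + 1L, ncol = 49L)
  for (a in 1:7) for (b in 1:7) {
    tp <- type_pair_index(a, b)
    eps <- sqrt(tt$eps[a] * tt$eps[b]); rmin <- tt$r0[a] + tt$r0[b]
    ftab[, tp] <- lj_pair(d, eps * rmin^12, 2 * eps * rmin^6) +
      pho_pair(d, tt$etr[a], tt$etr[b], tt$hydrophobic[a], tt$hydrophobic[b],
               tt$r0[a], tt$r0[b], ff$rsol)
    focc_i[, tp] <- occlusion_fraction(d, tt$r0[a], tt$r0[b], ff$rsol)
    focc_j[, tp] <- occlusion_fraction(d, tt$r0[b], tt$r0[a], ff$rsol)
  }
  # engine short-range table: hydrophobicity energy + the two occlusion
  # fractions, interleaved per bin, uniform in d^2 over [0, short_cut^2]
  # (both vanish once solvent-augmented spheres separate, < 6.5 A)
  short_cut <- 6.5
  nb2 <- 512L
  ds <- sqrt(seq(0, short_cut^2, length.out = nb2 + 1L))
  ds <- pmax(ds, 0.8)
  comb <- matrix(0, nrow = 3L * (nb2 + 1L), ncol = 49L)
  idx <- seq_len(nb2 + 1L)
  for (a in 1:7) for (b in 1:7) {
    tp <- type_pair_index(a, b)
    comb[3L * idx - 2L, tp] <-
      pho_pair(ds, tt$etr[a], tt$etr[b], tt$hydrophobic[a],
               tt$hydrophobic[b], tt$r0[a], tt$r0[b], ff$rsol)
    comb[3L * idx - 1L, tp] <- occlusion_fraction(ds, tt$r0[a], tt$r0[b],
                                                  ff$rsol)
    comb[3L * idx, tp] <- occlusion_fraction(ds, tt$r0[b], tt$r0[a],
                                             ff$rsol)
  }
  list(ftab = ftab, focc_i = focc_i, focc_j = focc_j, comb = comb,
       short_cut = short_cut)
}

# Everything the compiled engine needs for one sequence, built once.
# The apolar-environment burial weights w give the engine its transfer
# term: E_env = sum_i w_i * max(0, 1 - occ_i) with occ the pairwise
# occlusion sum; for the hydrophobic (membrane-like) environment
# w_i = -Etr_i * S_iso,i, so exposing polar surface to the apolar medium
# costs energy and exposing hydrophobic surface is favoured.
prepare_system <- function(sequence, ff = load_forcefield(),
                           hydrogen_policy = "polar") {
  topo <- peptide_topology(sequence, hydrogen_policy)
  atoms <- topo$atoms
  pp <- nonbonded_pairs(nrow(atoms), topo$bonds)
  # order pairs by residue-pair blocks so the engine can prune whole
  # blocks by CA-CA distance
  ri <- atoms$resid[pp[, 1]]; rj <- atoms$resid[pp[, 2]]
  qq0 <- ff$coulomb_k * atoms$q[pp[, 1]] * atoms$q[pp[, 2]]
  # neutral pairs first within each residue-pair block (branch-free sweep)
  ord <- order(ri, rj, qq0 != 0)
  pp <- pp[ord, , drop = FALSE]; ri <- ri[ord]; rj <- rj[ord]
  i <- pp[, 1]; j <- pp[, 2]
  qq <- qq0[ord]
  blk <- cumsum(!duplicated(cbind(ri, rj)))
  block_start <- c(0L, which(diff(blk) > 0), length(blk))
  nblock <- length(block_start) - 1L
  charged_start <- vapply(seq_len(nblock), function(b) {
    p1 <- block_start[b] + 1L; p2 <- block_start[b + 1L]
    ch <- which(qq[p1:p2] != 0)
    if (length(ch)) block_start[b] + ch[1] - 1L else p2
  }, integer(1))
  eps_p <- sqrt(ff$types$eps[atoms$type[i]] * ff$types$eps[atoms$type[j]])
  rmin_p <- ff$types$r0[atoms$type[i]] + ff$types$r0[atoms$type[j]]
  pairs <- list(
    i = i - 1L, j = j - 1L,
    tp = type_pair_index(atoms$type[i], atoms$type[j]) - 1L,
    qq = qq,
    A = eps_p * rmin_p^12, B = 2 * eps_p * rmin_p^6,
    heavy = atoms$element[i] != "H" & atoms$element[j] != "H",
    block_start = block_start,
    charged_start = charged_start,
    block_ri = ri[!duplicated(blk)] - 1L,
    block_rj = rj[!duplicated(blk)] - 1L)
  s_iso <- 4 * pi * (ff$types$r0[atoms$type] + ff$probe_radius)^2
  # per-residue CA atom index and bounding radius around CA (internal
  # geometry is rigid up to the psi-dependent carbonyl; +1 A margin)
  ca_idx <- vapply(seq_len(topo$n_res), function(r)
    which(atoms$resid == r & atoms$name == "CA")[1], integer(1))
  ref <- cpp_build_coords(topo$zmat$refa, topo$zmat$refb, topo$zmat$refc,
                          topo$zmat$bond, topo$zmat$ang, topo$zmat$dtype,
                          topo$zmat$dres, topo$zmat$doff,
                          rep(-57, topo$n_res), rep(-47, topo$n_res))
  reach <- vapply(seq_len(topo$n_res), function(r) {
    rows <- which(atoms$resid == r)
    max(sqrt(rowSums((ref[rows, , drop = FALSE] -
                      matrix(ref[ca_idx[r], ], length(rows), 3,
                             byrow = TRUE))^2)))
  }, numeric(1)) + 1.0
  tabs <- build_ftab(ff)
  list(sequence = sequence, topo = topo, pairs = pairs,
       pairs_1based = pp,
       ftab = tabs$ftab, comb = tabs$comb, short_cut = tabs$short_cut,
       s_iso = s_iso, ca_idx = ca_idx - 1L, reach = reach,
       w_apolar = -ff$types$etr[atoms$type] * s_iso,
       ff = ff)
}

# batch energies for a matrix of state assignments (rows = structures);
# w is the per-atom burial weight vector (zeros = no environment term)
system_energies <- function(sys, states, alphabet, w = sys$w_apolar) {
  cpp_energy_states(states, alphabet$states$phi, alphabet$states$psi,
                    sys$topo$zmat, sys$pairs, sys$comb, sys$short_cut, w,
                    sys$ca_idx, sys$reach, sys$ff$cutoff,
                    unname(sys$ff$diel))
}
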