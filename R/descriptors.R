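# Structure descriptors: Shrake-Rupley accessible surface area, the
# hydrophobic/hydrophilic area ratio (ASAr), dihedral + hydrogen-bond
# secondary-structure assignment, and superposition RMSD.

# Deterministic 162-point unit sphere: icosahedron subdivided twice
# (12 + 30 + 120 vertices).  Built once and cached.
icosphere_points <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    t <- (1 + sqrt(5)) / 2
    v <- rbind(
      c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
      c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
      c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
    v <- v / sqrt(rowSums(v^2))
    f <- rbind(
      c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
      c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
      c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
      c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
    for (iter in 1:2) {
      mid <- new.env(hash = TRUE)
      nf <- matrix(0L, nrow = 0, ncol = 3)
      getmid <- function(a, b) {
        key <- paste(min(a, b), max(a, b))
        if (!is.null(mid[[key]])) return(mid[[key]])
        m <- v[a, ] + v[b, ]
        m <- m / sqrt(sum(m^2))
        v <<- rbind(v, m)
        mid[[key]] <- nrow(v)
        nrow(v)
      }
      for (k in seq_len(nrow(f))) {
        a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
        ab <- getmid(a, b); bc <- getmid(b, c); ca <- getmid(c, a)
        nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc),
                    c(ab, bc, ca))
      }
      f <- nf
    }
    cache <<- v
    cache
  }
})

#' Shrake-Rupley accessible surface area
#'
#' Per-atom solvent-accessible surface area by deterministic 162-point
#' sphere sampling (twice-subdivided icosahedron), probe radius 1.4 A by
#' default, atom radii from the seven-type parameter table.
#'
#' @param x A `conformation`.
#' @param n_points Number of sphere points (the packaged point set has
#'   162; other values are rejected).
#' @param probe_radius Probe radius, Angstrom.
#' @param ff Force field supplying van der Waals radii.
#' @return A list of class `asa_result`: `atom` tibble (per-atom `asa`)
#'   and `residue` tibble (per-residue hydrophobic/hydrophilic area and
#'   `asar`, see [residue_asar()]).
#' @export
shrake_rupley_asa <- function(x, n_points = 162L, probe_radius = NULL,
                              ff = load_forcefield()) {
  if (n_points != 162L)
    stop("the packaged deterministic point set has 162 points", call. = FALSE)
  if (is.null(probe_radius)) probe_radius <- ff$probe_radius
  radii <- x$atoms$r0 + probe_radius
  asa <- cpp_asa(coords_matrix(x), radii, icosphere_points())
  atom <- tibble::tibble(resid = x$atoms$resid, name = x$atoms$name,
                         hydrophobic = x$atoms$hydrophobic, asa = asa)
  residue <- dplyr::summarise(
    dplyr::group_by(atom, .data$resid),
    asa_phob = sum(.data$asa[.data$hydrophobic]),
    asa_phil = sum(.data$asa[!.data$hydrophobic]),
    .groups = "drop")
  residue$asar <- asar_ratio(residue$asa_phob, residue$asa_phil)
  structure(list(atom = atom, residue = residue), class = "asa_result")
}

# capped ratio: a degenerate hydrophilic denominator (< 0.1 A^2) reports
# the cap value 99.9 so profile averages stay finite
asar_ratio <- function(phob, phil, eps_area = 0.1, cap = 99.9) {
  out <- ifelse(phil < eps_area, cap, phob / phil)
  pmin(out, cap)
}

#' Per-residue hydrophobic/hydrophilic surface ratio
#'
#' @param asa An `asa_result` from [shrake_rupley_asa()].
#' @return Tibble with `resid`, `asa_phob`, `asa_phil`, `asar`.
#' @export
residue_asar <- function(asa) {
  stopifnot(inherits(asa, "asa_result"))
  asa$residue
}

#' Secondary-structure assignment from dihedrals and hydrogen bonds
#'
#' A residue is helical when its phi/psi couple falls within an 80 deg
#' circle (wrapped angular distance) of the canonical helix point
#' (-57, -47) *and* it takes part in a backbone amide hydrogen bond
#' (H...O < 3 A) with the residue four positions away (alpha helix) or
#' three positions away (3-10 helix); the bond is accepted with the
#' residue as donor or as acceptor, whichever matches the helical
#' donor-to-earlier-acceptor geometry.  Beta is a 90 deg circle around
#' (-129, 123) on the dihedral criterion alone.  Everything else, and any
#' terminal residue lacking a defined phi or psi, is coil.
#'
#' @param x A `conformation` built with polar hydrogens.
#' @return Tibble with `residue`, `label` in
#'   `c("alpha_helix", "three_ten_helix", "beta", "coil")`.
#' @export
pex_assign <- function(x) {
  n <- nchar(x$sequence)
  has_h <- any(x$atoms$name == "H")
  if (!has_h && any(strsplit(x$sequence, "")[[1]] != "P"))
    stop("secondary-structure assignment needs backbone amide hydrogens; ",
         "rebuild with hydrogen_policy = \"polar\"", call. = FALSE)
  dih <- if (!is.null(x$dihedrals)) x$dihedrals else measure_dihedrals(x)
  xyz <- coords_matrix(x)
  hbond <- function(r_donor, r_acceptor) {
    ih <- atom_index(x, r_donor, "H"); io <- atom_index(x, r_acceptor, "O")
    if (is.na(ih) || is.na(io)) return(FALSE)
    sqrt(sum((xyz[ih, ] - xyz[io, ])^2)) < 3.0
  }
  label <- character(n)
  for (r in seq_len(n)) {
    phi <- dih$phi[r]; psi <- dih$psi[r]
    if (is.na(phi) || is.na(psi)) { label[r] <- "coil"; next }
    in_helix <- angle_dist(phi, psi, -57, -47) <= 80
    in_beta <- angle_dist(phi, psi, -129, 123) <= 90
    if (in_helix) {
      alpha <- (r + 4 <= n && hbond(r + 4, r)) || (r - 4 >= 1 && hbond(r, r - 4))
      three10 <- (r + 3 <= n && hbond(r + 3, r)) || (r - 3 >= 1 && hbond(r, r - 3))
      if (alpha) { label[r] <- "alpha_helix"; next }
      if (three10) { label[r] <- "three_ten_helix"; next }
    }
    label[r] <- if (in_beta) "beta" else "coil"
  }
  tibble::tibble(residue = seq_len(n), label = label)
}

helical_fraction <- function(labels) {
  mean(labels %in% c("alpha_helix", "three_ten_helix")) * 100
}

#' All-atom RMSD after optimal superposition
#'
#' Kabsch alignment of two conformations with identical atom counts.
#'
#' @param a,b Conformations (same sequence and atom ordering).
#' @return RMSD in Angstrom.
#' @export
superposed_rmsd <- function(a, b) {
  xa <- coords_matrix(a); xb <- coords_matrix(b)
  if (nrow(xa) != nrow(xb))
    stop("conformations have different atom counts (", nrow(xa), " vs ",
         nrow(xb), ")", call. = FALSE)
  kabsch_rmsd(xa, xb)
}

kabsch_rmsd <- function(xa, xb) {
  ca <- colMeans(xa); cb <- colMeans(xb)
  xa <- sweep(xa, 2, ca); xb <- sweep(xb, 2, cb)
  s <- svd(crossprod(xa, xb))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((xa %*% rot - xb)^2)))
}
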