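# Conformation container and the ideal-geometry all-atom builder.

#' Build an all-atom peptide conformation from alphabet states
#'
#' Constructs ideal-geometry coordinates (standard bond lengths and angles,
#' omega fixed at 180 deg, side chains in a single default rotamer) for a
#' sequence with one alphabet state per residue supplying its phi/psi
#' couple.  Polar backbone amide hydrogens are built under the default
#' hydrogen policy (they are required by the secondary-structure
#' assignment); apolar hydrogens are implicit in the heavy-atom types.
#'
#' @param sequence One-letter amino-acid string (20 standard codes).
#' @param state_indices Integer vector, one 1-based alphabet state per
#'   residue.
#' @param alphabet A [load_alphabet()] object.
#' @param hydrogen_policy `"polar"` (default) or `"none"`.
#' @param ff Force field used to annotate atoms.
#' @return A `conformation`: sequence, atom tibble (name, element, residue,
#'   type, charge, radius, transfer energy, coordinates in Angstrom),
#'   per-residue dihedrals and the state indices.
#' @export
build_conformation <- function(sequence, state_indices,
                               alphabet = load_alphabet(),
                               hydrogen_policy = c("polar", "none"),
                               ff = load_forcefield()) {
  hydrogen_policy <- match.arg(hydrogen_policy)
  n <- nchar(sequence)
  if (length(state_indices) != n)
    stop("length(state_indices) must equal the sequence length (",
         length(state_indices), " vs ", n, ")", call. = FALSE)
  topo <- peptide_topology(sequence, hydrogen_policy)
  phi <- alphabet$states$phi[state_indices]
  psi <- alphabet$states$psi[state_indices]
  xyz <- cpp_build_coords(topo$zmat$refa, topo$zmat$refb, topo$zmat$refc,
                          topo$zmat$bond, topo$zmat$ang, topo$zmat$dtype,
                          topo$zmat$dres, topo$zmat$doff, phi, psi)
  new_conformation(topo, xyz, ff,
                   dihedrals = tibble::tibble(
                     residue = seq_len(n),
                     phi = c(NA_real_, phi[-1]),
                     psi = c(psi[-n], NA_real_)),
                   state_indices = as.integer(state_indices))
}

new_conformation <- function(topo, xyz, ff, dihedrals = NULL,
                             state_indices = NULL) {
  atoms <- topo$atoms
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms$r0 <- ff$types$r0[atoms$type]
  atoms$etr <- ff$types$etr[atoms$type]
  atoms$hydrophobic <- ff$types$hydrophobic[atoms$type]
  structure(list(sequence = topo$sequence, atoms = atoms,
                 dihedrals = dihedrals, state_indices = state_indices,
                 bonds = topo$bonds),
            class = "conformation")
}

#' Assemble a conformation from an explicit atom table
#'
#' Escape hatch for toys, fixtures and externally loaded structures: takes
#' a data frame with coordinates and (a subset of) atom annotations and
#' returns a `conformation` usable by the energy and descriptor functions.
#' Columns `x`, `y`, `z` are required; `type` (1-7) drives any missing
#' annotation; `name`, `resid`, `q` default sensibly.
#'
#' @param atoms Data frame of atoms.
#' @param bonds Optional 2-column matrix of 1-based bonded atom index
#'   pairs (used for non-bonded exclusions); default none.
#' @param sequence Optional one-letter sequence.
#' @param ff Force field for type-derived annotation.
#' @return A `conformation`.
#' @export
conformation_from_atoms <- function(atoms, bonds = NULL, sequence = NA_character_,
                                    ff = load_forcefield()) {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("x", "y", "z") %in% names(atoms)))
  n <- nrow(atoms)
  if (is.null(atoms[["type"]])) atoms$type <- rep(1L, n)
  if (is.null(atoms[["name"]])) atoms$name <- paste0("X", seq_len(n))
  if (is.null(atoms[["element"]])) atoms$element <- atom_element(atoms$name)
  if (is.null(atoms[["resid"]])) atoms$resid <- rep(1L, n)
  if (is.null(atoms[["restype"]])) atoms$restype <- rep("A", n)
  if (is.null(atoms[["q"]])) atoms$q <- rep(0, n)
  if (is.null(atoms[["r0"]])) atoms$r0 <- ff$types$r0[atoms$type]
  if (is.null(atoms[["etr"]])) atoms$etr <- ff$types$etr[atoms$type]
  if (is.null(atoms[["hydrophobic"]]))
    atoms$hydrophobic <- ff$types$hydrophobic[atoms$type]
  if (is.null(bonds)) bonds <- cbind(i = integer(0), j = integer(0))
  structure(list(sequence = sequence, atoms = atoms, dihedrals = NULL,
                 state_indices = NULL, bonds = bonds),
            class = "conformation")
}

coords_matrix <- function(x) {
  as.matrix(x$atoms[, c("x", "y", "z")])
}

set_coords <- function(x, xyz) {
  x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
  x
}

atom_index <- function(x, resid, name) {
  k <- which(x$atoms$resid == resid & x$atoms$name == name)
  if (length(k)) k[[1]] else NA_integer_
}

#' Measure backbone dihedrals of a conformation
#'
#' @param x A `conformation` with backbone atoms N, CA, C.
#' @return Tibble with `residue`, `phi`, `psi` in degrees; `NA` where a
#'   terminal residue lacks the flanking atoms.
#' @export
measure_dihedrals <- function(x) {
  n <- nchar(x$sequence)
  xyz <- coords_matrix(x)
  ii <- function(r, nm) atom_index(x, r, nm)
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  quads <- list(); what <- list()
  for (r in seq_len(n)) {
    if (r > 1)
      { quads[[length(quads) + 1]] <- c(ii(r - 1, "C"), ii(r, "N"),
                                        ii(r, "CA"), ii(r, "C"))
        what[[length(what) + 1]] <- c("phi", r) }
    if (r < n)
      { quads[[length(quads) + 1]] <- c(ii(r, "N"), ii(r, "CA"),
                                        ii(r, "C"), ii(r + 1, "N"))
        what[[length(what) + 1]] <- c("psi", r) }
  }
  if (length(quads)) {
    vals <- cpp_measure_dihedrals(xyz, do.call(rbind, quads))
    for (k in seq_along(vals)) {
      r <- as.integer(what[[k]][2])
      if (what[[k]][1] == "phi") phi[r] <- vals[k] else psi[r] <- vals[k]
    }
  }
  tibble::tibble(residue = seq_len(n), phi = phi, psi = psi)
}

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation> ", x$sequence, " (", nrow(x$atoms), " atoms)\n",
      sep = "")
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.conformation <- function(x, ...) x$atoms

# rigid-body helpers (tests and fixtures)
transform_conformation <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- coords_matrix(x) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  set_coords(x, xyz)
}

#' Minimum distance between non-bonded heavy atoms
#'
#' The hard clash floor used by the sampler: structures with a non-bonded
#' heavy-atom pair closer than the floor (default 1.5 A) are resampled.
#'
#' @param x A `conformation`.
#' @return Minimum non-bonded heavy-atom distance, Angstrom.
#' @export
min_heavy_distance <- function(x) {
  pp <- nonbonded_pairs(nrow(x$atoms),
                        if (is.null(x$bonds)) cbind(i = integer(0), j = integer(0))
                        else x$bonds)
  hv <- x$atoms$element != "H"
  keep <- hv[pp[, 1]] & hv[pp[, 2]]
  if (!any(keep)) return(Inf)
  xyz <- coords_matrix(x)
  d <- sqrt(rowSums((xyz[pp[keep, 1], , drop = FALSE] -
                     xyz[pp[keep, 2], , drop = FALSE])^2))
  min(d)
}
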