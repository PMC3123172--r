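# Internal residue topology: ideal-geometry internal coordinates for the
# backbone and a single default rotamer per side chain.  Only phi/psi are
# sampled; omega is fixed trans (180 deg) and side-chain torsions are held
# at their most-populated rotamer.  Bond lengths in Angstrom, angles and
# dihedrals in degrees.  Polar backbone amide hydrogens are built when the
# hydrogen policy asks for them; apolar hydrogens are implicit in the
# heavy-atom types.

AA1 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", V = "VAL",
         W = "TRP", Y = "TYR")

# side-chain atom rows: name, refs a/b/c (atom names in the same residue),
# bond, angle, dihedral (constant; chi defaults baked in)
sc_row <- function(name, a, b, c, bond, ang, dih) {
  data.frame(name = name, a = a, b = b, c = c, bond = bond, ang = ang,
             dih = dih, stringsAsFactors = FALSE)
}

.cb <- sc_row("CB", "CA", "N", "C", 1.530, 110.5, -122.5)

sidechain_table <- local({
  rows <- function(...) do.call(rbind, list(...))
  list(
    G = NULL,
    A = .cb,
    S = rows(.cb, sc_row("OG",  "CB", "CA", "N", 1.417, 110.8, -60)),
    C = rows(.cb, sc_row("SG",  "CB", "CA", "N", 1.808, 113.8, -60)),
    T = rows(.cb, sc_row("OG1", "CB", "CA", "N", 1.430, 109.6, -60),
                  sc_row("CG2", "CB", "CA", "N", 1.520, 110.5, 178)),
    V = rows(.cb, sc_row("CG1", "CB", "CA", "N", 1.520, 110.5, -60),
                  sc_row("CG2", "CB", "CA", "N", 1.520, 110.5, 178)),
    L = rows(.cb, sc_row("CG",  "CB", "CA", "N", 1.530, 116.3, -60),
                  sc_row("CD1", "CG", "CB", "CA", 1.520, 110.7, 180),
                  sc_row("CD2", "CG", "CB", "CA", 1.520, 110.7, -60)),
    I = rows(.cb, sc_row("CG1", "CB", "CA", "N", 1.530, 110.4, -60),
                  sc_row("CG2", "CB", "CA", "N", 1.530, 110.5, 178),
                  sc_row("CD1", "CG1", "CB", "CA", 1.520, 113.8, 170)),
    P = rows(.cb, sc_row("CG",  "CB", "CA", "N", 1.490, 104.5, 30),
                  sc_row("CD",  "CG", "CB", "CA", 1.500, 106.1, -35)),
    M = rows(.cb, sc_row("CG",  "CB", "CA", "N", 1.520, 114.1, -60),
                  sc_row("SD",  "CG", "CB", "CA", 1.810, 112.7, 180),
                  sc_row("CE",  "SD", "CG", "CB", 1.790, 100.9, 180)),
    K = rows(.cb, sc_row("CG",  "CB", "CA", "N", 1.520, 114.1, -60),
                  sc_row("CD",  "CG", "CB", "CA", 1.520, 111.3, 180),
                  sc_row("CE",  "CD", "CG", "CB", 1.520, 111.3, 180),
                  sc_row("NZ",  "CE", "CD", "CG", 1.490, 111.9, 180)),
    R = rows(.cb, sc_row("CG",  "CB", "CA", "N", 1.520, 114.1, -60),
                  sc_row("CD",  "CG", "CB", "CA", 1.520, 111.3, 180),
                  sc_row("NE",  "CD", "CG", "CB", 1.460, 111.5, 180),
                  sc_row("CZ",  "NE", "CD", "CG", 1.330, 124.2, 180),
                  sc_row("NH1", "CZ", "NE", "CD", 1.330, 120.0, 0),
                  sc_row("NH2", "CZ", "NE", "CD", 1.330, 120.0, 180)),
    D = rows(.cb, sc_row("CG",  "CB", "CA", "N", 1.520, 112.6, -60),
                  sc_row("OD1", "CG", "CB", "CA", 1.250, 118.4, 0),
                  sc_row("OD2", "CG", "CB", "CA", 1.250, 118.4, 180)),
    N = rows(.cb, sc_row("CG",  "CB", "CA", "N", 1.520, 112.6, -60),
                  sc_row("OD1", "CG", "CB", "CA", 1.230, 120.8, 0),
                  sc_row("ND2", "CG", "CB", "CA", 1.330, 116.4, 180)),
    E = rows(.cb, sc_row("CG",  "CB", "CA", "N", 1.520, 114.1, -60),
                  sc_row("CD",  "CG", "CB", "CA", 1.520, 112.6, 180),
                  sc_row("OE1", "CD", "CG", "CB", 1.250, 118.4, 0),
                  sc_row("OE2", "CD", "CG", "CB", 1.250, 118.4, 180)),
    Q = rows(.cb, sc_row("CG",  "CB", "CA", "N", 1.520, 114.1, -60),
                  sc_row("CD",  "CG", "CB", "CA", 1.520, 112.6, 180),
                  sc_row("OE1", "CD", "CG", "CB", 1.230, 120.8, 0),
                  sc_row("NE2", "CD", "CG", "CB", 1.330, 116.4, 180)),
    F = rows(.cb, sc_row("CG",  "CB", "CA", "N", 1.500, 113.8, 180),
                  sc_row("CD1", "CG", "CB", "CA", 1.390, 120.8, 90),
                  sc_row("CD2", "CG", "CB", "CA", 1.390, 120.8, -90),
                  sc_row("CE1", "CD1", "CG", "CD2", 1.390, 120.0, 180),
                  sc_row("CE2", "CD2", "CG", "CD1", 1.390, 120.0, 180),
                  sc_row("CZ",  "CE1", "CD1", "CG", 1.390, 120.0, 0)),
    Y = rows(.cb, sc_row("CG",  "CB", "CA", "N", 1.500, 113.8, 180),
                  sc_row("CD1", "CG", "CB", "CA", 1.390, 120.8, 90),
                  sc_row("CD2", "CG", "CB", "CA", 1.390, 120.8, -90),
                  sc_row("CE1", "CD1", "CG", "CD2", 1.390, 120.0, 180),
                  sc_row("CE2", "CD2", "CG", "CD1", 1.390, 120.0, 180),
                  sc_row("CZ",  "CE1", "CD1", "CG", 1.390, 120.0, 0),
                  sc_row("OH",  "CZ", "CE1", "CD1", 1.380, 120.0, 180)),
    H = rows(.cb, sc_row("CG",  "CB", "CA", "N", 1.500, 113.8, 180),
                  sc_row("ND1", "CG", "CB", "CA", 1.380, 122.7, -90),
                  sc_row("CD2", "CG", "CB", "CA", 1.360, 129.7, 90),
                  sc_row("CE1", "ND1", "CG", "CD2", 1.320, 109.0, 0),
                  sc_row("NE2", "CD2", "CG", "ND1", 1.370, 107.0, 0)),
    W = rows(.cb, sc_row("CG",  "CB", "CA", "N", 1.500, 113.8, 180),
                  sc_row("CD1", "CG", "CB", "CA", 1.370, 127.0, -90),
                  sc_row("CD2", "CG", "CB", "CA", 1.430, 126.6, 90),
                  sc_row("NE1", "CD1", "CG", "CD2", 1.380, 110.0, 0),
                  sc_row("CE2", "CD2", "CG", "CD1", 1.410, 107.0, 0),
                  sc_row("CE3", "CD2", "CG", "CD1", 1.400, 133.9, 180),
                  sc_row("CZ2", "CE2", "CD2", "CE3", 1.400, 122.4, 0),
                  sc_row("CZ3", "CE3", "CD2", "CE2", 1.400, 118.8, 0),
                  sc_row("CH2", "CZ2", "CE2", "CD2", 1.370, 117.5, 0))
  )
})

# bonds internal to a side chain that the Z-matrix parent edges do not carry
# (ring closures); needed for the non-bonded exclusion graph
ring_closures <- list(
  F = rbind(c("CE2", "CZ")),
  Y = rbind(c("CE2", "CZ")),
  H = rbind(c("CE1", "NE2")),
  W = rbind(c("NE1", "CE2"), c("CZ3", "CH2")),
  P = rbind(c("CD", "N"))
)

# stand-in partial charges (fractions of unit charge); residues carry their
# formal net charge, uncharged polar groups a local dipole
backbone_charges <- c(N = -0.28, H = 0.28, C = 0.38, O = -0.38)
sidechain_charges <- list(
  S = c(CB = 0.25, OG = -0.25),
  T = c(CB = 0.25, OG1 = -0.25),
  Y = c(CZ = 0.25, OH = -0.25),
  C = c(CB = 0.10, SG = -0.10),
  N = c(CG = 0.38, OD1 = -0.38),
  Q = c(CD = 0.38, OE1 = -0.38),
  D = c(CG = 0.40, OD1 = -0.70, OD2 = -0.70),
  E = c(CD = 0.40, OE1 = -0.70, OE2 = -0.70),
  K = c(CE = 0.30, NZ = 0.70),
  R = c(CD = 0.10, NE = 0.20, CZ = 0.30, NH1 = 0.20, NH2 = 0.20),
  H = c(CG = 0.05, ND1 = -0.20, CD2 = 0.10, CE1 = 0.30, NE2 = -0.25),
  W = c(CD1 = 0.15, NE1 = -0.25, CE2 = 0.10),
  P = c(CD = 0.28)
)

charged_atoms <- list(
  N = c("NZ"),                        # element N carrying formal charge
  O = c("OD1", "OD2", "OE1", "OE2")   # carboxylate oxygens
)
charged_N_residues <- c(K = "NZ")
sp2_carbons <- list(
  F = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  Y = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  W = c("CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  H = c("CG", "CD2", "CE1"),
  D = c("CG"), E = c("CD"), N = c("CG"), Q = c("CD"), R = c("CZ")
)

#' @keywords internal
atom_element <- function(name) substr(name, 1L, 1L)

# Seven-type atomic classification:
# 1 aliphatic C, 2 sp2/aromatic C, 3 neutral N, 4 neutral O, 5 S,
# 6 charged N/O, 7 polar H.
assign_atom_type <- function(res1, atom) {
  el <- atom_element(atom)
  if (el == "H") return(7L)
  if (el == "S") return(5L)
  if (el == "N") {
    if (atom == "NZ" && res1 == "K") return(6L)
    if (res1 == "R" && atom %in% c("NE", "NH1", "NH2")) return(6L)
    return(3L)
  }
  if (el == "O") {
    if (res1 == "D" && atom %in% c("OD1", "OD2")) return(6L)
    if (res1 == "E" && atom %in% c("OE1", "OE2")) return(6L)
    return(4L)
  }
  # carbon
  if (atom == "C") return(2L)  # backbone carbonyl
  if (!is.null(sp2_carbons[[res1]]) && atom %in% sp2_carbons[[res1]])
    return(2L)
  1L
}

assign_charge <- function(res1, atom) {
  if (atom %in% names(backbone_charges)) {
    if (res1 == "P" && atom == "N") return(-0.28)
    return(unname(backbone_charges[atom]))
  }
  sc <- sidechain_charges[[res1]]
  if (!is.null(sc) && atom %in% names(sc)) return(unname(sc[atom]))
  0
}

# Full atom table + Z-matrix for a sequence.  Returns the pieces consumed
# by the compiled builder plus bookkeeping used everywhere else.
peptide_topology <- function(sequence, hydrogen_policy = "polar") {
  letters1 <- strsplit(sequence, "")[[1]]
  bad <- setdiff(letters1, names(AA1))
  if (length(bad))
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  n <- length(letters1)
  with_h <- identical(hydrogen_policy, "polar")

  name <- character(0); resid <- integer(0)
  refa <- integer(0); refb <- integer(0); refc <- integer(0)
  bond <- numeric(0); ang <- numeric(0)
  dtype <- integer(0); dres <- integer(0); doff <- numeric(0)
  bonds_i <- integer(0); bonds_j <- integer(0)

  idx <- function(r, nm) {
    k <- which(resid == r & name == nm)
    if (!length(k)) stop("internal: missing atom ", nm, " in residue ", r)
    k[[1]]
  }
  add <- function(nm, r, a, b, c, bd, an, dt, dr, off, bonded_to) {
    name <<- c(name, nm); resid <<- c(resid, r)
    refa <<- c(refa, a); refb <<- c(refb, b); refc <<- c(refc, c)
    bond <<- c(bond, bd); ang <<- c(ang, an)
    dtype <<- c(dtype, dt); dres <<- c(dres, dr); doff <<- c(doff, off)
    if (!is.na(bonded_to)) {
      bonds_i <<- c(bonds_i, length(name)); bonds_j <<- c(bonds_j, bonded_to)
    }
    length(name)
  }

  for (r in seq_len(n)) {
    aa <- letters1[r]
    if (r == 1L) {
      iN  <- add("N",  r, -1L, -1L, -1L, 0, 0, 0L, 0L, 0, NA)
      iCA <- add("CA", r, iN - 1L, -1L, -1L, 1.458, 0, 0L, 0L, 0, iN)
      iC  <- add("C",  r, iCA - 1L, iN - 1L, -1L, 1.525, 111.2, 0L, 0L, 0, iCA)
      if (with_h && aa != "P")
        add("H", r, iN - 1L, iCA - 1L, iC - 1L, 1.010, 119.5, 0L, 0L, 180, iN)
    } else {
      pC <- idx(r - 1L, "C"); pCA <- idx(r - 1L, "CA"); pO <- idx(r - 1L, "O")
      iN  <- add("N",  r, pC - 1L, pCA - 1L, idx(r - 1L, "N") - 1L,
                 1.329, 116.2, 2L, r - 2L, 0, pC)
      if (with_h && aa != "P")
        add("H", r, iN - 1L, pC - 1L, pO - 1L, 1.010, 119.5, 0L, 0L, 180, iN)
      iCA <- add("CA", r, iN - 1L, pC - 1L, pCA - 1L, 1.458, 121.7,
                 0L, 0L, 180, iN)
      iC  <- add("C",  r, iCA - 1L, iN - 1L, pC - 1L, 1.525, 111.2,
                 1L, r - 1L, 0, iCA)
    }
    add("O", r, iC - 1L, iCA - 1L, iN - 1L, 1.231, 120.5, 2L, r - 1L, 180, iC)
    sc <- sidechain_table[[aa]]
    if (!is.null(sc)) {
      for (k in seq_len(nrow(sc))) {
        ia <- idx(r, sc$a[k])
        add(sc$name[k], r, ia - 1L, idx(r, sc$b[k]) - 1L,
            idx(r, sc$c[k]) - 1L, sc$bond[k], sc$ang[k], 0L, 0L, sc$dih[k], ia)
      }
    }
    rc <- ring_closures[[aa]]
    if (!is.null(rc)) {
      for (k in seq_len(nrow(rc))) {
        bonds_i <- c(bonds_i, idx(r, rc[k, 1]))
        bonds_j <- c(bonds_j, idx(r, rc[k, 2]))
      }
    }
  }

  restype <- letters1[resid]
  type <- mapply(assign_atom_type, restype, name)
  q <- mapply(assign_charge, restype, name)

  list(
    sequence = sequence, n_res = n,
    atoms = tibble::tibble(
      name = name, element = atom_element(name), resid = resid,
      restype = restype, type = as.integer(type), q = as.numeric(q)),
    zmat = list(refa = refa, refb = refb, refc = refc, bond = bond,
                ang = ang, dtype = dtype, dres = dres, doff = doff),
    bonds = cbind(i = bonds_i, j = bonds_j)
  )
}

# 1-2/1-3 exclusions from the bond graph; everything else (1-4 and beyond)
# is a full-weight non-bonded pair.
nonbonded_pairs <- function(natoms, bonds) {
  adj <- vector("list", natoms)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  excl <- new.env(hash = TRUE)
  mark <- function(i, j) {
    if (i != j) assign(paste(min(i, j), max(i, j)), TRUE, envir = excl)
  }
  for (i in seq_len(natoms)) {
    for (j in adj[[i]]) {
      mark(i, j)
      for (k in adj[[j]]) mark(i, k)
    }
  }
  all_i <- rep(seq_len(natoms - 1L), times = (natoms - 1L):1L)
  all_j <- unlist(lapply(seq_len(natoms - 1L), function(i) (i + 1L):natoms))
  keep <- !vapply(paste(all_i, all_j), exists, logical(1), envir = excl,
                  inherits = FALSE)
  cbind(i = all_i[keep], j = all_j[keep])
}
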