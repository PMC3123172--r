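# Deterministic synthetic fixtures: TMD-like sequences and reference
# conformations used by examples, calibration and tests.

#' Generate a synthetic fixture
#'
#' Deterministic generators for the study conditions used throughout the
#' package:
#'
#' * `synthetic_tmd`: a TMD-like sequence - a 19-residue hydrophobic core
#'   (residues drawn from L/I/V/F/A) flanked on each side by 5 charged or
#'   polar residues mimicking juxta-membrane composition: acidic residues
#'   on the N-terminal/extracellular flank, Lys/Arg on the
#'   C-terminal/cytosolic flank, an interfacial tryptophan on both sides
#'   (interfacial aromatics occur at both membrane interfaces), with the
#'   two flanks mirror-symmetric in residue class so the core midpoint is
#'   also the physical insertion center.
#' * `poly_leu_helix` / `poly_lys_helix`: 19-mer ideal alpha helices of
#'   leucine (hydrophobic control) or lysine (charged control).
#' * `ideal_alpha_coords` / `extended_coords`: poly-alanine conformations
#'   built on the alphabet state nearest the canonical helix (-57, -47)
#'   or extended (-129, 123) point.
#' * `two_bundle_modelset`: a `model_set` stub of two tight structural
#'   bundles far apart (clustering fixture).
#'
#' @param kind Fixture kind (see above).
#' @param length Sequence length where applicable.
#' @param seed Integer seed; identical seeds give identical fixtures.
#' @param alphabet,ff Model components.
#' @return A character sequence or a `conformation`/`model_set`,
#'   depending on `kind`.
#' @export
generate_fixture <- function(kind = c("synthetic_tmd", "poly_leu_helix",
                                      "poly_lys_helix", "ideal_alpha_coords",
                                      "extended_coords", "two_bundle_modelset"),
                             length = NULL, seed = 1L,
                             alphabet = load_alphabet(),
                             ff = load_forcefield()) {
  kind <- match.arg(kind)
  helix <- nearest_state(alphabet, -57, -47)
  ext <- nearest_state(alphabet, -129, 123)
  build_helix <- function(seq1)
    build_conformation(seq1, rep(helix, nchar(seq1)), alphabet, ff = ff)
  switch(kind,
    synthetic_tmd = {
      if (is.null(length)) length <- 29L
      core_len <- length - 10L
      if (core_len < 1L)
        stop("synthetic_tmd needs length >= 11 (two 5-residue flanks)",
             call. = FALSE)
      withr::with_seed(seed, {
        core <- paste(sample(c("L", "I", "V", "F", "A"), core_len,
                             replace = TRUE,
                             prob = c(0.35, 0.2, 0.2, 0.15, 0.1)),
                      collapse = "")
        paste0("DEWSE", core, "KSWRK")
      })
    },
    poly_leu_helix = {
      if (is.null(length)) length <- 19L
      build_helix(strrep("L", length))
    },
    poly_lys_helix = {
      if (is.null(length)) length <- 19L
      build_helix(strrep("K", length))
    },
    ideal_alpha_coords = {
      if (is.null(length)) length <- 19L
      build_helix(strrep("A", length))
    },
    extended_coords = {
      if (is.null(length)) length <- 19L
      build_conformation(strrep("A", length), rep(ext, length), alphabet,
                         ff = ff)
    },
    two_bundle_modelset = {
      if (is.null(length)) length <- 9L
      base1 <- build_helix(strrep("A", length))
      base2 <- build_conformation(strrep("A", length), rep(ext, length),
                                  alphabet, ff = ff)
      jitter_conf <- function(conf, k) {
        xyz <- coords_matrix(conf)
        withr::with_seed(seed * 1000L + k,
                         xyz <- xyz + matrix(stats::rnorm(base::length(xyz), 0, 0.05),
                                             ncol = 3))
        set_coords(conf, xyz)
      }
      models <- c(lapply(1:5, function(k) jitter_conf(base1, k)),
                  lapply(6:10, function(k) jitter_conf(base2, k)))
      structure(list(sequence = strrep("A", length),
                     environment = "hydrophobic", models = models,
                     energies = seq(-10, -1, length.out = 10),
                     states = NULL, prime = models[[1]], seed = seed),
                class = "model_set")
    })
}
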