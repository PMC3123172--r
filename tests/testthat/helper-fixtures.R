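# Shared model components, loaded once per test run.
FF <- load_forcefield()
AL <- load_alphabet()
HELIX_STATE <- nearest_state(AL, -57, -47)
EXT_STATE <- nearest_state(AL, -129, 123)
MB <- membrane_model(FF)

helix_conf <- function(seq1) {
  build_conformation(seq1, rep(HELIX_STATE, nchar(seq1)), AL, ff = FF)
}

random_rotation_matrix <- function(seed) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(9), 3)
    q <- qr.Q(qr(m))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

# toy four-state alphabet (helix, extended, two turns) used by the
# sampler-vs-enumeration checks
toy_alphabet <- function() {
  make_alphabet(phi = c(-57, -129, -80, 60),
                psi = c(-47, 123, 0, 40))
}

# stub window with constant per-residue statistics (bookkeeping tests)
stub_window <- function(start, window_length = 19L, end_exclusion = 4L,
                        n_models = 99L, helical = TRUE, asar = 5,
                        mfp = 100, z = 0) {
  keep <- (end_exclusion + 1L):(window_length - end_exclusion)
  structure(list(
    start = start, center = start + (window_length - 1L) %/% 2L,
    stats = tibble::tibble(
      pos = start + keep - 1L, n = n_models,
      n_helical = if (helical) n_models else 0L,
      asar_sum = asar * n_models, mfp_sum = mfp * n_models),
    mean_best_z = z), class = "tmd_window")
}
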