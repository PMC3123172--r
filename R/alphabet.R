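# The 64-state backbone dihedral alphabet and its per-position sampling
# probabilities.

#' Load the backbone structural alphabet
#'
#' Reads the packaged (or user-supplied) table of 64 phi/psi couples and
#' attaches uniform initial sampling probabilities (1/64 for every state at
#' every sequence position).  The packaged table was derived by k-means
#' clustering (on the torus embedding) of dihedral pairs harvested from a
#' small nonredundant set of reference chains; see the file header for
#' provenance.  It is a versioned, user-replaceable stand-in for a
#' PDB-wide structural alphabet.
#'
#' @param path Path to a whitespace-separated table `index phi psi`
#'   (degrees); default packaged table.
#' @param n_positions Number of sequence positions for which to initialize
#'   probability vectors.
#' @return A `structural_alphabet`: list with `states` (tibble of 64 rows:
#'   `index`, `phi`, `psi`) and `probabilities` (64 x n_positions matrix,
#'   each column summing to 1).
#' @export
load_alphabet <- function(path = NULL, n_positions = 1L) {
  if (is.null(path))
    path <- system.file("extdata", "alphabet64.tsv", package = "tmdscan")
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("index", "phi", "psi"))
  if (nrow(tab) != 64L)
    stop("alphabet table must contain exactly 64 states, found ",
         nrow(tab), " (missing indices: ",
         paste(setdiff(1:64, tab$index), collapse = ", "), ")",
         call. = FALSE)
  if (any(tab$phi <= -180 | tab$phi > 180 | tab$psi <= -180 | tab$psi > 180))
    stop("alphabet angles must lie in (-180, 180]", call. = FALSE)
  new_alphabet(tibble::as_tibble(tab), n_positions)
}

new_alphabet <- function(states, n_positions = 1L) {
  n_states <- nrow(states)
  probs <- matrix(1 / n_states, nrow = n_states, ncol = n_positions)
  structure(list(states = states, probabilities = probs),
            class = "structural_alphabet")
}

#' Build a small custom alphabet
#'
#' Mainly for toys and oracle tests: wraps an explicit table of phi/psi
#' couples (any number of states) in the same container as
#' [load_alphabet()].
#'
#' @param phi,psi Numeric vectors of equal length, degrees in (-180, 180].
#' @param n_positions Number of positions for the probability matrix.
#' @return A `structural_alphabet`.
#' @export
make_alphabet <- function(phi, psi, n_positions = 1L) {
  stopifnot(length(phi) == length(psi))
  new_alphabet(tibble::tibble(index = seq_along(phi), phi = phi, psi = psi),
               n_positions)
}

#' @export
print.structural_alphabet <- function(x, ...) {
  cat("<structural_alphabet>", nrow(x$states), "states,",
      ncol(x$probabilities), "position(s)\n")
  invisible(x)
}

# wrapped angular distance between (phi, psi) couples, degrees
angle_dist <- function(phi1, psi1, phi2, psi2) {
  w <- function(x) {
    x <- abs(x) %% 360
    pmin(x, 360 - x)
  }
  sqrt(w(phi1 - phi2)^2 + w(psi1 - psi2)^2)
}

#' Nearest alphabet state to a phi/psi couple
#'
#' @param alphabet A `structural_alphabet`.
#' @param phi,psi Target angles, degrees.
#' @return The 1-based state index minimizing the wrapped angular distance.
#' @export
nearest_state <- function(alphabet, phi, psi) {
  which.min(angle_dist(alphabet$states$phi, alphabet$states$psi, phi, psi))
}

# validity used by the sampler after every probability update
check_probabilities <- function(probs, floor = 0) {
  sums <- colSums(probs)
  if (any(abs(sums - 1) > 1e-9))
    stop("probability columns must sum to 1", call. = FALSE)
  if (any(probs < floor - 1e-12))
    stop("probability below floor", call. = FALSE)
  invisible(TRUE)
}
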