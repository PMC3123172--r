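# Residue-environment (mean-force-potential) percentage: how complete a
# residue's non-bonded atomic environment is, expressed as a percentage of
# a per-residue-type calibrated mean.

#' Residue environment score
#'
#' Sum of the non-bonded Lennard-Jones + hydrophobicity pair terms between
#' the atoms of one residue and all atoms of *other* residues within the
#' cutoff (10 A by default).  More negative means a more complete, more
#' stabilizing atomic envelope.
#'
#' @param x A `conformation`.
#' @param residue_index 1-based residue index, or `NULL` for all residues.
#' @param cutoff Environment cutoff, Angstrom.
#' @param ff Force field.
#' @return Numeric score(s), kJ/mol.
#' @export
residue_environment_score <- function(x, residue_index = NULL, cutoff = 10,
                                      ff = load_forcefield()) {
  n <- max(x$atoms$resid)
  if (!is.null(residue_index) &&
      (any(residue_index < 1) || any(residue_index > n)))
    stop("residue index out of range 1..", n, call. = FALSE)
  pp <- nonbonded_pairs(nrow(x$atoms),
                        if (is.null(x$bonds)) cbind(i = integer(0), j = integer(0))
                        else x$bonds)
  pairs <- list(i = pp[, 1] - 1L, j = pp[, 2] - 1L,
                tp = type_pair_index(x$atoms$type[pp[, 1]],
                                     x$atoms$type[pp[, 2]]) - 1L,
                qq = rep(0, nrow(pp)),
                heavy = rep(TRUE, nrow(pp)))
  scores <- cpp_env_scores(coords_matrix(x), pairs, x$atoms$resid, n,
                           build_ftab(ff)$ftab, ff$cutoff, cutoff)
  if (is.null(residue_index)) scores else scores[residue_index]
}

#' Calibrate per-residue-type mean environment scores
#'
#' Computes the mean (and dispersion) of [residue_environment_score()] per
#' residue type over a set of reference conformations.  The packaged
#' calibration uses the package's own fixture structures and is labelled
#' non-canonical: supply your own optimized reference set for production
#' use.
#'
#' @param reference_structures List of `conformation` objects jointly
#'   covering all 20 residue types.
#' @param cutoff,ff Passed to [residue_environment_score()].
#' @param provenance Free-text provenance note stored with the
#'   calibration.
#' @return An `mfp_calibration`: tibble of per-type `mean_score`, `sd`,
#'   `n`, plus provenance metadata.
#' @export
calibrate_mfp <- function(reference_structures, cutoff = 10,
                          ff = load_forcefield(),
                          provenance = "user-supplied reference set") {
  obs <- purrr::map_dfr(reference_structures, function(conf) {
    sc <- residue_environment_score(conf, cutoff = cutoff, ff = ff)
    tibble::tibble(restype = conf$atoms$restype[!duplicated(conf$atoms$resid)],
                   score = sc)
  })
  missing <- setdiff(names(AA1), unique(obs$restype))
  if (length(missing))
    stop("reference set lacks residue type(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab <- dplyr::summarise(dplyr::group_by(obs, .data$restype),
                          mean_score = mean(.data$score),
                          sd = stats::sd(.data$score),
                          n = dplyr::n(), .groups = "drop")
  structure(list(table = tab, cutoff = cutoff,
                 provenance = provenance, date = as.character(Sys.Date())),
            class = "mfp_calibration")
}

#' @export
print.mfp_calibration <- function(x, ...) {
  cat("<mfp_calibration>", nrow(x$table), "residue types, cutoff",
      x$cutoff, "A -", x$provenance, "\n")
  invisible(x)
}

#' Packaged fixture calibration
#'
#' Environment-score calibration computed from synthetic helical host
#' peptides: each of the 20 residue types is embedded, glycine-spaced
#' (every fifth position, so guest side chains never touch), in three
#' ideal poly-glycine helices with the guests in different orders.  This
#' gives every type a clean, reproducible helical reference environment.
#' Non-canonical: a convenience default so profiles can always report a
#' percentage; see [calibrate_mfp()] to calibrate on a curated reference
#' set.
#'
#' @param ff Force field.
#' @return An `mfp_calibration`.
#' @export
default_mfp_calibration <- function(ff = load_forcefield()) {
  calibrate_mfp(mfp_reference_structures(ff), ff = ff,
                provenance = "packaged glycine-host fixtures (non-canonical)")
}

# the packaged reference set behind default_mfp_calibration()
mfp_reference_structures <- function(ff = load_forcefield()) {
  alphabet <- load_alphabet()
  helix <- nearest_state(alphabet, -57, -47)
  ext <- nearest_state(alphabet, -129, 123)
  types <- setdiff(names(AA1), "P")
  orders <- list(types, rev(types), c(types[10:19], types[1:9]))
  refs <- lapply(orders, function(tt) {
    s <- paste0("GG", paste0(tt, "GGGG", collapse = ""))
    build_conformation(s, rep(helix, nchar(s)), alphabet, ff = ff)
  })
  # proline is referenced in an extended host: a rigid ideal helix is not
  # a conformation proline can adopt (i-4 carbonyl clash)
  pro <- "GGPGGGGPGGGGPGG"
  c(refs, list(build_conformation(pro, rep(ext, nchar(pro)), alphabet,
                                  ff = ff)))
}

#' Environment percentage per residue
#'
#' 100 x score / calibrated mean for the residue's type, clipped to
#' \[0, 200\].  Interpretation: above ~60% the residue sits in a stable,
#' nearly complete atomic environment; below ~40% it would need an
#' intermolecular interaction (lipid, partner chain) to be stabilized.
#'
#' @param x A `conformation`.
#' @param calibration An [calibrate_mfp()] object covering every residue
#'   type present.
#' @param ff Force field.
#' @return Tibble with `residue`, `restype`, `score`, `mfp_pct`.
#' @export
mfp_percentage <- function(x, calibration = default_mfp_calibration(),
                           ff = load_forcefield()) {
  sc <- residue_environment_score(x, cutoff = calibration$cutoff, ff = ff)
  restype <- x$atoms$restype[!duplicated(x$atoms$resid)]
  missing <- setdiff(unique(restype), calibration$table$restype)
  if (length(missing))
    stop("calibration lacks residue type(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  mean_score <- calibration$table$mean_score[
    match(restype, calibration$table$restype)]
  pct <- pmin(200, pmax(0, 100 * sc / mean_score))
  tibble::tibble(residue = seq_along(sc), restype = restype,
                 score = sc, mfp_pct = pct)
}
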