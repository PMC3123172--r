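# Sliding-window scan: per-window modelling, per-residue aggregation of
# helicity / ASAr / membrane insertion / environment percentage, and the
# TMD center and limit calls.

#' Scan configuration
#'
#' @param window_length Window length in residues (odd; default 19, the
#'   longest window whose models stay within ~1 A mutual RMSD).
#' @param shift Window shift (1).
#' @param end_exclusion Residues excluded at each window extremity when
#'   aggregating per-residue statistics (4).
#' @param asar_smoothing_window Moving-average window for the ASAr column
#'   (5 residues).
#' @param insertion_smoothing_window Moving-average window for the
#'   insertion-depth column (7 window centers; 3 is also in circulation,
#'   see the methods vignette).
#' @param helicity_threshold Minimum mean helicity (%) for a residue span
#'   to count as helical (75).
#' @param span_cap Maximum TMD span in residues retained by the limit
#'   call (26, consistent with a <= 30 deg tilt across the core plus
#'   interfaces).
#' @param environment Sampler energy environment for window peptides.
#' @param sampler A [sampler_config()].
#' @param insertion_tilt_step,insertion_spin_step Deterministic
#'   orientation grid (degrees) for the per-model insertion scans of the
#'   pipeline (coarser and noise-free compared to the standalone
#'   [insertion_scan()] random default; see the vignette).
#' @param insertion_z_step z step (A) of the pipeline insertion scans.
#' @param master_seed Master seed; each window derives its own seed.
#' @return A `scan_config` list.
#' @export
scan_config <- function(window_length = 19L, shift = 1L, end_exclusion = 4L,
                        asar_smoothing_window = 5L,
                        insertion_smoothing_window = 7L,
                        helicity_threshold = 75,
                        span_cap = 26L,
                        environment = "hydrophobic",
                        sampler = sampler_config(),
                        insertion_tilt_step = 10, insertion_spin_step = 30,
                        insertion_z_step = 0.5,
                        master_seed = 1L) {
  window_length <- as.integer(window_length)
  end_exclusion <- as.integer(end_exclusion)
  if (window_length %% 2L == 0L || window_length < 2L * end_exclusion + 1L)
    stop("window_length must be odd and at least 2*end_exclusion + 1",
         call. = FALSE)
  if (asar_smoothing_window %% 2L == 0L ||
      insertion_smoothing_window %% 2L == 0L)
    stop("smoothing windows must be odd", call. = FALSE)
  structure(list(window_length = window_length, shift = as.integer(shift),
                 end_exclusion = end_exclusion,
                 asar_smoothing_window = as.integer(asar_smoothing_window),
                 insertion_smoothing_window = as.integer(insertion_smoothing_window),
                 helicity_threshold = helicity_threshold,
                 span_cap = as.integer(span_cap),
                 environment = environment, sampler = sampler,
                 insertion_tilt_step = insertion_tilt_step,
                 insertion_spin_step = insertion_spin_step,
                 insertion_z_step = insertion_z_step,
                 master_seed = as.integer(master_seed)),
            class = "scan_config")
}

window_seed <- function(master_seed, start) {
  as.integer((as.numeric(master_seed) * 10007 + 7919 * start) %% 2147483629)
}

#' Enumerate scan windows
#'
#' All contiguous windows of the configured length at the configured
#' shift, with 1-based inclusive offsets: window k covers residues
#' `start .. start + window_length - 1`.
#'
#' @param sequence One-letter sequence.
#' @param config A [scan_config()].
#' @return Tibble with `window`, `start`, `end`, `center`, `sequence`,
#'   `seed`.
#' @export
generate_windows <- function(sequence, config = scan_config()) {
  n <- nchar(sequence)
  w <- config$window_length
  if (n < w)
    stop("sequence (", n, " aa) is shorter than the ", w,
         "-residue window; model it directly with run_peplook()",
         call. = FALSE)
  starts <- seq.int(1L, n - w + 1L, by = config$shift)
  tibble::tibble(
    window = seq_along(starts), start = starts, end = starts + w - 1L,
    center = starts + (w - 1L) %/% 2L,
    sequence = vapply(starts, function(s) substr(sequence, s, s + w - 1L),
                      character(1)),
    seed = vapply(starts, function(s) window_seed(config$master_seed, s),
                  integer(1)))
}

#' Summarize one modelled window
#'
#' Reduces a window's model archive to the per-absolute-residue counts the
#' profile aggregation needs (models covering the residue outside the
#' 4-residue end exclusion; helical labels; ASAr; environment percentage)
#' plus the mean best insertion depth of the window's models.
#'
#' @param model_set A `model_set` for the window peptide.
#' @param start Absolute 1-based start offset of the window.
#' @param config A [scan_config()].
#' @param calibration Environment-percentage calibration.
#' @param membrane Membrane model.
#' @param ff Force field.
#' @return A `tmd_window`: list with `start`, `center`, `stats` tibble
#'   (`pos`, `n`, `n_helical`, `asar_sum`, `mfp_sum`) and `mean_best_z`,
#'   the mean unsigned best insertion depth |z| of the window's models
#'   (signed values cancel by bilayer symmetry).
#' @export
window_statistics <- function(model_set, start, config = scan_config(),
                              calibration = default_mfp_calibration(),
                              membrane = membrane_model(),
                              ff = load_forcefield()) {
  w <- config$window_length
  excl <- config$end_exclusion
  keep <- (excl + 1L):(w - excl)
  # deduplicate identical models (identical state strings) for descriptor
  # work; counts still reflect all models
  keys <- if (!is.null(model_set$states))
    apply(model_set$states, 1, paste, collapse = ",")
  else as.character(seq_along(model_set$models))
  uniq <- which(!duplicated(keys))
  mult <- as.vector(table(factor(keys, levels = keys[uniq])))

  # everything that does not depend on coordinates, prepared once
  first <- model_set$models[[1]]
  at <- first$atoms
  seq1 <- first$sequence
  sys <- prepare_system(seq1, ff)
  radii <- at$r0 + ff$probe_radius
  pts <- icosphere_points()
  phob <- at$hydrophobic
  resid <- at$resid
  restype <- at$restype[!duplicated(resid)]
  mean_score <- calibration$table$mean_score[
    match(restype, calibration$table$restype)]
  iH <- vapply(seq_len(w), function(r) {
    k <- which(resid == r & at$name == "H"); if (length(k)) k[1] else NA_integer_
  }, integer(1))
  iO <- vapply(seq_len(w), function(r) {
    k <- which(resid == r & at$name == "O"); if (length(k)) k[1] else NA_integer_
  }, integer(1))
  rots <- grid_rotations(config$insertion_tilt_step,
                         config$insertion_spin_step)
  zgrid <- seq(membrane$z_range[1], membrane$z_range[2],
               by = config$insertion_z_step)
  alip <- membrane$alip; etr <- at$etr
  env_pairs <- list(i = sys$pairs$i, j = sys$pairs$j, tp = sys$pairs$tp,
                    qq = rep(0, length(sys$pairs$i)),
                    heavy = rep(TRUE, length(sys$pairs$i)))

  n_hel <- matrix(0, nrow = length(uniq), ncol = length(keep))
  asar <- matrix(0, nrow = length(uniq), ncol = length(keep))
  mfp <- matrix(0, nrow = length(uniq), ncol = length(keep))
  best_z <- numeric(length(uniq))
  for (k in seq_along(uniq)) {
    conf <- model_set$models[[uniq[k]]]
    xyz <- coords_matrix(conf)
    lab <- pex_fast(conf$dihedrals, xyz, iH, iO)
    n_hel[k, ] <- lab[keep]
    asa <- cpp_asa(xyz, radii, pts)
    ap <- rowsum(asa * phob, resid)[, 1]
    ah <- rowsum(asa * !phob, resid)[, 1]
    asar[k, ] <- asar_ratio(ap, ah)[keep]
    sc <- cpp_env_scores(xyz, env_pairs, resid, w, sys$ftab,
                         ff$cutoff, calibration$cutoff)
    mfp[k, ] <- pmin(200, pmax(0, 100 * sc / mean_score))[keep]
    ins <- cpp_insertion_scan(xyz, asa * (alip - etr), rots, zgrid,
                              membrane$z0, membrane$alpha)
    # unsigned depth: the bilayer is symmetric, so signed best-z values
    # cancel across models and only the penetration depth is informative
    best_z[k] <- abs(ins$best_z)
  }
  stats <- tibble::tibble(
    pos = start + keep - 1L,
    n = sum(mult),
    n_helical = as.vector(crossprod(n_hel, mult)),
    asar_sum = as.vector(crossprod(asar, mult)),
    mfp_sum = as.vector(crossprod(mfp, mult)))
  structure(list(start = start, center = start + (w - 1L) %/% 2L,
                 stats = stats,
                 mean_best_z = sum(best_z * mult) / sum(mult)),
            class = "tmd_window")
}

# vectorized helical test (alpha or 3-10) used by the scan hot path;
# agrees with pex_assign() on the helical labels
pex_fast <- function(dih, xyz, iH, iO) {
  n <- nrow(dih)
  ok_dih <- !is.na(dih$phi) & !is.na(dih$psi) &
    angle_dist(dih$phi, dih$psi, -57, -47) <= 80
  hb <- function(da, db) {
    out <- rep(FALSE, n)
    src <- seq_len(n)
    dn <- src + da; ac <- src + db
    sel <- dn >= 1 & dn <= n & ac >= 1 & ac <= n
    hi <- iH[dn[sel]]; oi <- iO[ac[sel]]
    good <- !is.na(hi) & !is.na(oi)
    idx <- which(sel)[good]
    d <- sqrt(rowSums((xyz[hi[good], , drop = FALSE] -
                       xyz[oi[good], , drop = FALSE])^2))
    out[idx] <- d < 3.0
    out
  }
  # residue i participates in an i/i+4 or i/i+3 backbone H-bond with the
  # correct donor (H of the later residue) / acceptor (O of the earlier)
  bond4 <- hb(4, 0) | hb(0, -4)
  bond3 <- hb(3, 0) | hb(0, -3)
  ok_dih & (bond4 | bond3)
}

# centered moving average with shrinking edges; NA-aware
smooth_ma <- function(x, k) {
  h <- (k - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - h):min(n, i + h)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Aggregate per-window statistics into a residue profile
#'
#' For each residue of the full sequence: the number of covering model
#' structures (11 windows x 99 models = 1089 away from the ends), the
#' helicity percentage, the mean ASAr (raw and smoothed over 5 residues),
#' the mean best insertion depth of the windows centered there (raw and
#' smoothed over 7 window centers) and the mean environment percentage.
#'
#' @param windows List of [window_statistics()] results (or equivalently
#'   shaped stubs).
#' @param sequence Full target sequence.
#' @param config A [scan_config()].
#' @return A `residue_profile` tibble: `pos`, `aa`, `n_structs`,
#'   `helicity_pct`, `asar_raw`, `asar_smooth`, `z_raw`, `z_smooth`,
#'   `mfp_pct`.
#' @export
aggregate_profiles <- function(windows, sequence, config = scan_config()) {
  n <- nchar(sequence)
  starts <- vapply(windows, function(w) w$start, numeric(1))
  expected <- seq.int(1L, n - config$window_length + 1L, by = config$shift)
  miss <- setdiff(expected, starts)
  if (length(miss))
    stop("missing window(s) at offset(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  all_stats <- dplyr::bind_rows(lapply(windows, function(w) w$stats))
  agg <- dplyr::summarise(
    dplyr::group_by(all_stats, .data$pos),
    n_structs = sum(.data$n),
    helicity_pct = 100 * sum(.data$n_helical) / sum(.data$n),
    asar_raw = sum(.data$asar_sum) / sum(.data$n),
    mfp_pct = sum(.data$mfp_sum) / sum(.data$n),
    .groups = "drop")
  prof <- tibble::tibble(pos = seq_len(n),
                         aa = strsplit(sequence, "")[[1]])
  prof <- dplyr::left_join(prof, agg, by = "pos")
  prof$n_structs[is.na(prof$n_structs)] <- 0L
  prof$asar_smooth <- smooth_ma(prof$asar_raw, config$asar_smoothing_window)
  z <- rep(NA_real_, n)
  for (w in windows) z[w$center] <- w$mean_best_z
  prof$z_raw <- z
  prof$z_smooth <- rep(NA_real_, n)
  cen <- which(!is.na(z))
  if (length(cen))
    prof$z_smooth[cen] <- smooth_ma(z[cen],
                                    config$insertion_smoothing_window)
  prof <- prof[, c("pos", "aa", "n_structs", "helicity_pct", "asar_raw",
                   "asar_smooth", "z_raw", "z_smooth", "mfp_pct")]
  class(prof) <- c("residue_profile", class(prof))
  attr(prof, "sequence") <- sequence
  attr(prof, "config") <- config
  prof
}

#' Call the TMD central residue from a profile
#'
#' The center is the residue with the highest smoothed ASAr; the deepest
#' mean membrane insertion (smallest |z|) must corroborate it.  When the
#' insertion minimum falls on an adjacent residue the pair is reported as
#' a two-residue center; a discordance beyond one residue is flagged but
#' the ASAr maximum keeps priority.  Two near-equal ASAr maxima (within
#' 5%) raise a double-maximum flag and the insertion criterion arbitrates.
#' The mean helicity of the 18-residue span centered on the call must
#' reach the threshold (75%) or the call is flagged.
#'
#' @param profile A `residue_profile`.
#' @param config A [scan_config()] (thresholds).
#' @return A `tmd_call`: `center_residues`, `limits` (NA until
#'   [call_tmd_limits()]), `flags`, and a criteria `trace`.
#' @export
call_tmd_center <- function(profile, config = attr(profile, "config")) {
  if (is.null(config)) config <- scan_config()
  asar <- profile$asar_smooth
  flags <- character(0)
  if (all(is.na(asar)) || diff(range(asar, na.rm = TRUE)) < 1e-9)
    return(new_tmd_call(integer(0), c(NA, NA), "no_call_flat_profile",
                        list(reason = "flat or empty ASAr profile")))
  amax <- which.max(asar)
  zcol <- profile$z_smooth
  zmin <- if (all(is.na(zcol))) NA_integer_ else which.min(abs(zcol))
  # double/flat maximum: any non-adjacent residue within 5% of the
  # global maximum makes the ASAr criterion ambiguous (saturated
  # hydrophobic stretches plateau rather than peak)
  second <- setdiff(which(!is.na(asar) & asar >= 0.95 * asar[amax]), amax)
  second <- second[abs(second - amax) > 1L]
  center <- amax
  if (length(second)) {
    flags <- c(flags, "double_maximum")
    if (!is.na(zmin)) {
      # the insertion criterion arbitrates over the near-maximal ASAr
      # region: on a saturated hydrophobic stretch the per-residue ratio
      # varies 10-15% with side-chain size alone, so every residue
      # within 15% of the maximum is a candidate; the deepest-insertion
      # location is estimated by the centroid of the penetration-depth
      # profile, which averages over all windows and is robust to
      # single-window structural idiosyncrasy
      cand <- which(!is.na(asar) & asar >= 0.85 * asar[amax])
      cand <- cand[!is.na(zcol[cand])]
      if (!length(cand)) cand <- c(amax, second)
      ok <- which(!is.na(zcol))
      wgt <- pmax(0, max(zcol[ok]) - zcol[ok])
      depth_centroid <- if (sum(wgt) > 0) sum(wgt * ok) / sum(wgt)
                        else mean(ok)
      center <- cand[which.min(abs(cand - depth_centroid))]
    }
  }
  centers <- center
  if (!is.na(zmin)) {
    if (abs(zmin - center) == 1L) centers <- sort(c(center, zmin))
    else if (abs(zmin - center) > 1L)
      flags <- c(flags, "insertion_discordant")
  }
  # helicity of the 18-residue span centered on the call
  mid <- centers[1]
  span <- max(1L, mid - 8L):min(nrow(profile), mid + 9L)
  hel <- mean(profile$helicity_pct[span], na.rm = TRUE)
  if (!is.finite(hel) || hel < config$helicity_threshold) {
    flags <- c(flags, "helicity_below_threshold")
    if (!is.finite(hel) ||
        all(profile$helicity_pct < config$helicity_threshold, na.rm = TRUE))
      return(new_tmd_call(integer(0), c(NA, NA), c(flags, "no_call"),
                          list(reason = "no residue span reaches the helicity threshold",
                               asar_argmax = amax, insertion_argmin = zmin)))
  }
  new_tmd_call(centers, c(NA_integer_, NA_integer_), flags,
               list(asar_argmax = amax, insertion_argmin = zmin,
                    span_helicity = hel))
}

new_tmd_call <- function(centers, limits, flags, trace) {
  structure(list(center_residues = centers, limits = limits,
                 flags = flags, trace = trace),
            class = "tmd_call")
}

#' Call the TMD limits around a called center
#'
#' The limits span the maximal contiguous run of residues around the
#' center whose helicity stays at or above the threshold, truncated
#' symmetrically toward the center to the configured span cap (26
#' residues, the geometric limit for a <= 30 deg tilted helix crossing
#' the core plus interfaces), and clipped to the sequence bounds.
#'
#' @param profile A `residue_profile`.
#' @param call A `tmd_call` from [call_tmd_center()] (or an integer
#'   center).
#' @param config A [scan_config()].
#' @return The `tmd_call` with `limits` filled and flags updated.
#' @export
call_tmd_limits <- function(profile, call, config = attr(profile, "config")) {
  if (is.null(config)) config <- scan_config()
  if (is.numeric(call)) call <- new_tmd_call(as.integer(call), c(NA, NA),
                                             character(0), list())
  if (!length(call$center_residues)) return(call)
  n <- nrow(profile)
  mid <- call$center_residues[1]
  ok <- !is.na(profile$helicity_pct) &
    profile$helicity_pct >= config$helicity_threshold
  # treat uncovered terminal residues as extending the run only if inside
  # coverage nothing contradicts; uncovered = not helical for the run
  lo <- mid
  while (lo - 1L >= 1L && isTRUE(ok[lo - 1L])) lo <- lo - 1L
  hi <- mid
  while (hi + 1L <= n && isTRUE(ok[hi + 1L])) hi <- hi + 1L
  if (lo == 1L || hi == n) call$flags <- c(call$flags, "limits_at_sequence_bound")
  # symmetric trim toward the center to the span cap
  while (hi - lo + 1L > config$span_cap) {
    if (hi - mid > mid - lo) hi <- hi - 1L
    else if (mid - lo > hi - mid) lo <- lo + 1L
    else if ((hi - lo + 1L) %% 2L == 0L) hi <- hi - 1L
    else lo <- lo + 1L
  }
  if (hi - lo + 1L < 15L) call$flags <- c(call$flags, "short_tmd")
  call$limits <- c(lo, hi)
  call
}

#' @export
print.tmd_call <- function(x, ...) {
  if (!length(x$center_residues)) {
    cat("<tmd_call> no call (", paste(x$flags, collapse = ", "), ")\n")
    return(invisible(x))
  }
  cat("<tmd_call> center ", paste(x$center_residues, collapse = "/"),
      if (!any(is.na(x$limits)))
        paste0(", limits ", x$limits[1], "-", x$limits[2]),
      if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Tidy a TMD call
#'
#' @param x A `tmd_call`.
#' @param ... Unused.
#' @return One-row tibble: centers, limits, span, flags.
#' @export
tidy.tmd_call <- function(x, ...) {
  tibble::tibble(
    center = if (length(x$center_residues)) x$center_residues[1] else NA_integer_,
    center2 = if (length(x$center_residues) > 1) x$center_residues[2] else NA_integer_,
    limit_first = x$limits[1], limit_last = x$limits[2],
    span = if (any(is.na(x$limits))) NA_integer_ else diff(x$limits) + 1L,
    flags = paste(x$flags, collapse = ";"))
}

#' Scan a sequence and call its transmembrane domain
#'
#' The full pipeline: slide the window along the sequence, model each
#' window peptide with [run_peplook()], summarize each window with
#' [window_statistics()], aggregate into a [aggregate_profiles()] residue
#' profile, and call the TMD center and limits.
#'
#' @param sequence One-letter sequence (at least one window long).
#' @param config A [scan_config()].
#' @param alphabet,ff,calibration,membrane Model components (packaged
#'   defaults).
#' @param keep_models Keep the per-window model archives in the result
#'   (memory-heavy; off by default).
#' @param progress Print per-window progress.
#' @param memo_store Optional environment used as a per-window-sequence
#'   store of persistent energy memos ([peplook_memo()]); sharing one
#'   store across repeated scans of the same sequence (e.g. several
#'   master seeds) avoids re-evaluating identical conformations.
#' @return A `tmd_scan` object: `profile`, `call`, `windows` tibble,
#'   `manifest` (seeds and configuration snapshot for exact re-runs).
#' @export
tmd_scan <- function(sequence, config = scan_config(),
                     alphabet = load_alphabet(), ff = load_forcefield(),
                     calibration = default_mfp_calibration(ff),
                     membrane = membrane_model(ff),
                     keep_models = FALSE, progress = FALSE,
                     memo_store = NULL) {
  sequence <- toupper(sequence)
  wins <- generate_windows(sequence, config)
  results <- vector("list", nrow(wins))
  models <- if (keep_models) vector("list", nrow(wins)) else NULL
  for (k in seq_len(nrow(wins))) {
    if (progress)
      message(sprintf("window %d/%d (%s, seed %d)", k, nrow(wins),
                      wins$sequence[k], wins$seed[k]))
    memo <- NULL
    if (!is.null(memo_store)) {
      if (is.null(memo_store[[wins$sequence[k]]]))
        memo_store[[wins$sequence[k]]] <- peplook_memo()
      memo <- memo_store[[wins$sequence[k]]]
    }
    ms <- run_peplook(wins$sequence[k], environment = config$environment,
                      config = config$sampler, alphabet = alphabet,
                      ff = ff, seed = wins$seed[k], memo = memo)
    results[[k]] <- window_statistics(ms, wins$start[k], config,
                                      calibration, membrane, ff)
    if (keep_models) models[[k]] <- ms
  }
  profile <- aggregate_profiles(results, sequence, config)
  call <- call_tmd_limits(profile, call_tmd_center(profile, config), config)
  structure(list(sequence = sequence, profile = profile, call = call,
                 windows = wins, window_results = results,
                 models = models,
                 manifest = run_manifest(sequence, config, wins)),
            class = "tmd_scan")
}

#' @export
print.tmd_scan <- function(x, ...) {
  cat("<tmd_scan> ", nchar(x$sequence), " residues, ", nrow(x$windows),
      " windows\n", sep = "")
  print(x$call)
  invisible(x)
}

#' @rdname tmd_scan
#' @param x A `tmd_scan`.
#' @param ... Unused.
#' @export
tidy.tmd_scan <- function(x, ...) tibble::as_tibble(x$profile)

#' @rdname tmd_scan
#' @export
glance.tmd_scan <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_residues = nchar(x$sequence),
                   n_windows = nrow(x$windows)),
    tidy(x$call))
}

#' Average aligned residue profiles across species
#'
#' Maps each species' residue profile onto the columns of a supplied
#' alignment (gaps carry no values), averages every profile column
#' position-wise across species (unweighted), and re-runs the center and
#' limit calls on the consensus.  Species whose own ASAr maximum falls
#' more than one column from the consensus maximum are flagged as
#' anomalous (the isolated double-maximum situation).
#'
#' @param profiles Named list of `residue_profile` objects.
#' @param aligned Named character vector of aligned sequences (same names,
#'   `-` for gaps); ungapped sequences must match the profiled ones.
#' @param config A [scan_config()].
#' @return A `tmd_consensus`: consensus profile (by alignment column),
#'   `call`, and per-species anomaly flags.
#' @export
multispecies_consensus <- function(profiles, aligned,
                                   config = scan_config()) {
  if (length(profiles) < 2L)
    stop("need at least two species profiles", call. = FALSE)
  if (is.null(names(profiles)) || !all(names(profiles) %in% names(aligned)))
    stop("profiles and alignment must share species names", call. = FALSE)
  ncol_aln <- unique(nchar(aligned))
  if (length(ncol_aln) != 1L)
    stop("aligned sequences must all have the same length", call. = FALSE)
  num_cols <- c("n_structs", "helicity_pct", "asar_raw", "asar_smooth",
                "z_raw", "z_smooth", "mfp_pct")
  mapped <- lapply(names(profiles), function(sp) {
    aa <- strsplit(aligned[[sp]], "")[[1]]
    idx <- which(aa != "-")
    prof <- profiles[[sp]]
    if (length(idx) != nrow(prof))
      stop("alignment for ", sp, " does not match its profile length",
           call. = FALSE)
    out <- tibble::tibble(column = seq_len(ncol_aln), aa = aa)
    for (cc in num_cols) {
      v <- rep(NA_real_, ncol_aln)
      v[idx] <- prof[[cc]]
      out[[cc]] <- v
    }
    out
  })
  names(mapped) <- names(profiles)
  cons <- mapped[[1]][, c("column", "aa")]
  for (cc in num_cols) {
    mat <- vapply(mapped, function(m) m[[cc]], numeric(ncol_aln))
    cons[[cc]] <- rowMeans(mat, na.rm = TRUE)
    cons[[cc]][is.nan(cons[[cc]])] <- NA_real_
  }
  names(cons)[names(cons) == "column"] <- "pos"
  class(cons) <- c("residue_profile", class(cons))
  attr(cons, "config") <- config
  call <- call_tmd_limits(cons, call_tmd_center(cons, config), config)
  cons_max <- which.max(cons$asar_smooth)
  anomalies <- vapply(mapped, function(m) {
    sp_max <- which.max(m$asar_smooth)
    abs(sp_max - cons_max) > 1L
  }, logical(1))
  structure(list(profile = cons, call = call, anomalies = anomalies,
                 species = names(profiles)),
            class = "tmd_consensus")
}

#' @export
print.tmd_consensus <- function(x, ...) {
  cat("<tmd_consensus> ", length(x$species), " species\n", sep = "")
  print(x$call)
  if (any(x$anomalies))
    cat("anomalous species:", paste(x$species[x$anomalies], collapse = ", "),
        "\n")
  invisible(x)
}

run_manifest <- function(sequence, config, windows) {
  list(package_version = as.character(utils::packageVersion("tmdscan")),
       date = as.character(Sys.time()),
       sequence = sequence,
       sequence_sha = substr(paste(utils::head(
         strtoi(charToRaw(sequence), 16L), 50), collapse = ""), 1, 64),
       master_seed = config$master_seed,
       window_seeds = stats::setNames(windows$seed, windows$start),
       config = unclass(config)[setdiff(names(config), "sampler")],
       sampler = unclass(config$sampler))
}
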