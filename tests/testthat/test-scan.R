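test_that("window enumeration covers the sequence at shift one", {
  cfg <- scan_config()
  w30 <- generate_windows(strrep("A", 30), cfg)
  expect_equal(nrow(w30), 12L)
  w19 <- generate_windows(strrep("A", 19), cfg)
  expect_equal(nrow(w19), 1L)
  expect_equal(w30$start[3], 3L)
  expect_equal(w30$end[3], 21L)
  expect_equal(w30$center[3], 12L)
  expect_equal(nchar(w30$sequence[1]), 19L)
  expect_error(generate_windows(strrep("A", 10), cfg), "shorter")
  expect_error(scan_config(window_length = 18L), "odd")
  expect_error(scan_config(asar_smoothing_window = 4L), "odd")
})

test_that("window seeds are deterministic 32-bit integers", {
  s1 <- tmdscan:::window_seed(1L, 5L)
  expect_identical(s1, tmdscan:::window_seed(1L, 5L))
  expect_true(s1 > 0 && s1 < 2^31)
  expect_false(s1 == tmdscan:::window_seed(2L, 5L))
})

test_that("interior residues are covered by 11 windows x 99 models", {
  n <- 34L
  cfg <- scan_config()
  starts <- seq_len(n - 19L + 1L)
  wins <- lapply(starts, stub_window)
  prof <- aggregate_profiles(wins, strrep("A", n), cfg)
  # enumeration oracle: windows whose 4-residue-excluded interior covers r
  oracle <- vapply(seq_len(n), function(r) {
    sum(vapply(starts, function(s) {
      p <- r - s + 1L
      p >= 5L && p <= 15L
    }, logical(1)))
  }, integer(1))
  expect_equal(prof$n_structs, oracle * 99L)
  interior <- seq(15L, n - 14L)
  expect_true(all(prof$n_structs[interior] == 1089L))
  # residue 5 is reachable by exactly one window interior
  expect_equal(prof$n_structs[5], 99L)
  expect_equal(prof$n_structs[1], 0L)
  # missing window errors with its offset
  expect_error(aggregate_profiles(wins[-3], strrep("A", n), cfg),
               "offset.*3")
})

test_that("constant inputs survive aggregation and smoothing unchanged", {
  starts <- 1:6
  wins <- lapply(starts, stub_window, asar = 4.2, mfp = 80, z = -1.5)
  prof <- aggregate_profiles(wins, strrep("A", 24), scan_config())
  covered <- prof$n_structs > 0
  expect_true(all(abs(prof$asar_raw[covered] - 4.2) < 1e-12))
  expect_true(all(abs(prof$asar_smooth[covered] - 4.2) < 1e-12))
  expect_true(all(abs(prof$mfp_pct[covered] - 80) < 1e-12))
  cen <- !is.na(prof$z_raw)
  expect_true(all(abs(prof$z_smooth[cen] + 1.5) < 1e-12))
  expect_equal(prof$helicity_pct[covered], rep(100, sum(covered)))
})

test_that("center calling follows ASAr with insertion corroboration", {
  mk_prof <- function(asar, z, hel = 90) {
    n <- length(asar)
    prof <- tibble::tibble(pos = 1:n, aa = rep("L", n), n_structs = 99L,
                           helicity_pct = rep(hel, n), asar_raw = asar,
                           asar_smooth = asar, z_raw = z, z_smooth = z,
                           mfp_pct = 100)
    class(prof) <- c("residue_profile", class(prof))
    attr(prof, "config") <- scan_config()
    prof
  }
  n <- 25
  bump <- function(center, width = 6) exp(-((1:n) - center)^2 / width^2)
  # unimodal agreement: both criteria at 12
  call1 <- call_tmd_center(mk_prof(2 + 3 * bump(12), 5 - 4.9 * bump(12)))
  expect_equal(call1$center_residues, 12L)
  expect_false("insertion_discordant" %in% call1$flags)
  # ASAr at 12, insertion at 15: ASAr keeps priority, discordance flagged
  call2 <- call_tmd_center(mk_prof(2 + 3 * bump(12), 5 - 4.9 * bump(15)))
  expect_equal(call2$center_residues[1], 12L)
  expect_true("insertion_discordant" %in% call2$flags)
  # insertion argmin adjacent: two-residue center
  call3 <- call_tmd_center(mk_prof(2 + 3 * bump(12),
                                   5 - 4.9 * bump(13, width = 2)))
  expect_equal(call3$center_residues, c(12L, 13L))
  # two near-equal maxima: flagged, insertion arbitrates
  twin <- 2 + 3 * pmax(bump(8, 2), 0.99 * bump(17, 2))
  call4 <- call_tmd_center(mk_prof(twin, 5 - 4.9 * bump(17, 2)))
  expect_true("double_maximum" %in% call4$flags)
  expect_equal(call4$center_residues[1], 17L)
  # flat profile: no call
  call5 <- call_tmd_center(mk_prof(rep(3, n), rep(0, n)))
  expect_length(call5$center_residues, 0)
  # nothing helical anywhere: no call with diagnostics
  call6 <- call_tmd_center(mk_prof(2 + 3 * bump(12), 5 - 4.9 * bump(12),
                                   hel = 40))
  expect_length(call6$center_residues, 0)
  expect_true("no_call" %in% call6$flags)
})

test_that("limits follow the helical run, the span cap and the bounds", {
  mk <- function(hel) {
    n <- length(hel)
    prof <- tibble::tibble(pos = 1:n, aa = "L", n_structs = 99L,
                           helicity_pct = hel, asar_raw = 3, asar_smooth = 3,
                           z_raw = 0, z_smooth = 0, mfp_pct = 100)
    class(prof) <- c("residue_profile", class(prof))
    attr(prof, "config") <- scan_config()
    prof
  }
  hel <- rep(90, 40)
  hel[c(1:7, 34:40)] <- 50
  call <- call_tmd_limits(mk(hel), 20L)
  expect_equal(call$limits, c(8L, 33L))       # span 26 = exactly the cap
  # a dip on the N side moves the limit in
  hel2 <- hel; hel2[14] <- 60
  call2 <- call_tmd_limits(mk(hel2), 20L)
  expect_equal(call2$limits[1], 15L)
  # an over-long run is trimmed symmetrically toward the center
  hel3 <- rep(90, 40)
  call3 <- call_tmd_limits(mk(hel3), 20L)
  expect_equal(diff(call3$limits) + 1L, 26L)
  expect_true("limits_at_sequence_bound" %in% call3$flags)
  # a short run is flagged
  hel4 <- rep(50, 40); hel4[18:24] <- 90
  call4 <- call_tmd_limits(mk(hel4), 20L)
  expect_true("short_tmd" %in% call4$flags)
})

test_that("multi-species consensus averages columns and flags anomalies", {
  mk_prof <- function(asar) {
    n <- length(asar)
    prof <- tibble::tibble(pos = 1:n, aa = "L", n_structs = 99L,
                           helicity_pct = 90, asar_raw = asar,
                           asar_smooth = asar, z_raw = 0, z_smooth = 0,
                           mfp_pct = 100)
    class(prof) <- c("residue_profile", class(prof))
    prof
  }
  n <- 25
  bump <- function(center) 2 + 3 * exp(-((1:n) - center)^2 / 16)
  aligned <- c(a = strrep("L", n), b = strrep("L", n), c = strrep("L", n))
  same <- list(a = mk_prof(bump(12)), b = mk_prof(bump(12)),
               c = mk_prof(bump(12)))
  cons <- multispecies_consensus(same, aligned, scan_config())
  expect_equal(cons$profile$asar_smooth, bump(12))
  expect_false(any(cons$anomalies))
  # a spurious second maximum in one species
  odd <- bump(12); odd[20] <- max(odd) * 1.02
  mixed <- list(a = mk_prof(odd), b = mk_prof(bump(12)), c = mk_prof(bump(12)))
  cons2 <- multispecies_consensus(mixed, aligned, scan_config())
  expect_true(cons2$anomalies[["a"]])
  expect_equal(which.max(cons2$profile$asar_smooth), 12L)
  # hand-computed mean on a 3-species toy
  p1 <- mk_prof(rep(1, n)); p2 <- mk_prof(rep(2, n)); p3 <- mk_prof(rep(6, n))
  cons3 <- multispecies_consensus(list(a = p1, b = p2, c = p3), aligned,
                                  scan_config())
  expect_equal(cons3$profile$asar_raw, rep(3, n))
  # gapped alignment maps values to columns
  aligned2 <- c(a = paste0("--", strrep("L", n)),
                b = paste0(strrep("L", n), "--"))
  cons4 <- multispecies_consensus(list(a = mk_prof(bump(12)),
                                       b = mk_prof(bump(12))),
                                  aligned2, scan_config())
  expect_equal(nrow(cons4$profile), n + 2L)
  expect_error(multispecies_consensus(list(a = p1), aligned, scan_config()),
               "two species")
})

test_that("the fast window summaries agree with the reference descriptors", {
  toy <- toy_alphabet()
  seq19 <- strrep("L", 19)
  cfg <- scan_config(sampler = sampler_config(structures_per_step = 50,
                                              total_steps = 5))
  ms <- run_peplook(seq19, "hydrophobic", cfg$sampler, AL, FF, seed = 2)
  cal <- default_mfp_calibration(FF)
  ws <- window_statistics(ms, 1L, cfg, cal, MB, FF)
  expect_equal(ws$stats$n, rep(length(ms$models), 11))
  # reference recomputation for one model, one position
  conf <- ms$models[[1]]
  lab <- pex_assign(conf)$label
  ra <- residue_asar(shrake_rupley_asa(conf, ff = FF))
  mp <- mfp_percentage(conf, cal, FF)
  keys <- apply(ms$states, 1, paste, collapse = ",")
  mult <- as.integer(table(factor(keys, levels = unique(keys))))
  uniq <- !duplicated(keys)
  labs <- vapply(ms$models[uniq], function(m)
    pex_assign(m)$label[10] %in% c("alpha_helix", "three_ten_helix"),
    logical(1))
  expect_equal(ws$stats$n_helical[ws$stats$pos == 10], sum(labs * mult))
  asars <- vapply(ms$models[uniq], function(m)
    residue_asar(shrake_rupley_asa(m, ff = FF))$asar[10], numeric(1))
  expect_equal(ws$stats$asar_sum[ws$stats$pos == 10], sum(asars * mult),
               tolerance = 1e-9)
})
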