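CAL <- default_mfp_calibration(FF)

test_that("an isolated residue has zero environment score", {
  # two residues 60 A apart (beyond any cutoff): both see nothing
  a <- helix_conf("AA")
  xyz <- tmdscan:::coords_matrix(a)
  xyz[a$atoms$resid == 2, ] <- xyz[a$atoms$resid == 2, ] + 60
  far <- tmdscan:::set_coords(a, xyz)
  expect_equal(residue_environment_score(far, ff = FF), c(0, 0))
  expect_error(residue_environment_score(a, residue_index = 5, ff = FF),
               "out of range")
})

test_that("an enveloped helix interior scores lower than a stretched chain", {
  hel <- helix_conf(strrep("L", 11))
  ext <- build_conformation(strrep("L", 11), rep(EXT_STATE, 11), AL, ff = FF)
  expect_lt(residue_environment_score(hel, 6, ff = FF),
            residue_environment_score(ext, 6, ff = FF))
})

test_that("environment scores are rigid-motion invariant", {
  conf <- helix_conf("LKAYV")
  moved <- tmdscan:::transform_conformation(conf, random_rotation_matrix(8),
                                            c(3, -7, 12))
  expect_equal(residue_environment_score(conf, ff = FF),
               residue_environment_score(moved, ff = FF), tolerance = 1e-6)
})

test_that("calibration is an exact per-type mean and duplication-invariant", {
  refs <- list(helix_conf(paste(names(tmdscan:::AA1), collapse = "")))
  cal1 <- calibrate_mfp(refs, ff = FF)
  sc <- residue_environment_score(refs[[1]], ff = FF)
  expect_equal(cal1$table$mean_score[cal1$table$restype == "L"],
               sc[11])
  cal2 <- calibrate_mfp(c(refs, refs), ff = FF)
  expect_equal(cal1$table$mean_score, cal2$table$mean_score)
  expect_error(calibrate_mfp(list(helix_conf("AAA")), ff = FF),
               "lacks residue type")
})

test_that("percentages are score over calibrated mean, clipped to [0, 200]", {
  conf <- helix_conf("GGGLGGG")
  pct <- mfp_percentage(conf, CAL, FF)
  expect_equal(nrow(pct), 7L)
  expect_true(all(pct$mfp_pct >= 0 & pct$mfp_pct <= 200))
  # a residue scoring exactly its calibrated mean reports 100%
  fake <- CAL
  sc <- residue_environment_score(conf, 4, cutoff = CAL$cutoff, ff = FF)
  fake$table$mean_score[fake$table$restype == "L"] <- sc
  expect_equal(mfp_percentage(conf, fake, FF)$mfp_pct[4], 100)
  # helix interior is better enveloped than the terminus
  hel <- helix_conf(strrep("A", 11))
  p <- mfp_percentage(hel, CAL, FF)
  expect_gt(p$mfp_pct[6], p$mfp_pct[1])
})

test_that("calibrate-then-score on the calibration set averages 100% per type", {
  refs <- list(helix_conf(paste(names(tmdscan:::AA1), collapse = "")),
               helix_conf(paste(rev(names(tmdscan:::AA1)), collapse = "")))
  cal <- calibrate_mfp(refs, ff = FF)
  pct <- dplyr::bind_rows(lapply(refs, mfp_percentage, calibration = cal,
                                 ff = FF))
  bytype <- tapply(pct$mfp_pct, pct$restype, mean)
  clipped <- tapply(pct$mfp_pct, pct$restype,
                    function(v) any(v %in% c(0, 200)))
  expect_equal(as.numeric(bytype[!clipped]),
               rep(100, sum(!clipped)), tolerance = 1e-6)
  expect_gt(sum(!clipped), 10)
})
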