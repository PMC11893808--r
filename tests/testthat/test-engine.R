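test_that("MDL filter thresholds peaks at mdl_factor times the noise level", {
  peaks <- data.frame(mz = c(200, 300, 400), intensity = c(1, 10, 100))
  kept <- mdl_filter(peaks, mdl_factor = 2, noise_level = 4)
  expect_equal(kept$intensity, c(10, 100))
  expect_error(mdl_filter(peaks, mdl_factor = 0), "positive")
  expect_equal(nrow(mdl_filter(peaks[0, ])), 0)

  # planted noise floor: retained set equals direct thresholding
  set.seed(1)
  signal <- data.frame(mz = runif(60, 150, 700),
                       intensity = runif(60, 50, 500))
  noise <- data.frame(mz = runif(40, 150, 700),
                      intensity = runif(40, 0.5, 1.5))
  spec <- rbind(signal, noise)
  kept <- mdl_filter(spec, mdl_factor = 2)
  thr <- attr(kept, "mdl")
  expect_equal(sort(kept$intensity), sort(spec$intensity[spec$intensity >= thr]))
  expect_true(all(signal$intensity %in% kept$intensity))
})

test_that("mean-mode recalibration removes a constructed ppm shift and is idempotent", {
  cal <- seq(200, 600, by = 40)            # 11 calibrants
  peaks <- data.frame(mz = cal * (1 + 0.3e-6), intensity = 1000)
  out <- recalibrate(peaks, cal, noise_level = 1)
  resid <- mean((out$mz - cal) / cal * 1e6)
  expect_lt(abs(resid), 1e-4)
  expect_equal(attr(out, "ppm_correction"), 0.3, tolerance = 1e-6)

  # zero shift: output equals input
  peaks0 <- data.frame(mz = cal, intensity = 1000)
  out0 <- recalibrate(peaks0, cal, noise_level = 1)
  expect_equal(out0$mz, cal, tolerance = 1e-12)

  # second application changes m/z by < 1e-6 ppm
  out2 <- recalibrate(out, cal, noise_level = 1)
  expect_lt(max(abs((out2$mz - out$mz) / out$mz * 1e6)), 1e-6)

  # fewer than 3 matched calibrants is an explicit error
  expect_error(recalibrate(peaks, cal[1:2], noise_level = 1),
               "3 matched calibrant")
  # calibrants below the signal/MDL requirement do not match
  weak <- data.frame(mz = cal, intensity = 3)
  expect_error(recalibrate(weak, cal, noise_level = 1), "3 matched calibrant")
})

test_that("formula enumeration equals the exhaustive nested-loop oracle", {
  ec <- element_constraints()
  # anhydrohexose mass with heteroatoms disabled: unique hit
  ecn <- element_constraints(n = c(0L, 0L), s = c(0L, 0L), p = c(0L, 0L))
  hit <- enumerate_formulas(162.052823, 0.5, ecn)
  expect_equal(hit$formula, "C6H10O5")
  # far below the lightest valid formula: empty
  expect_equal(nrow(enumerate_formulas(10, 10, ec)), 0)
  # random masses against the oracle (full 200-mass sweep in acceptance)
  set.seed(7)
  for (m in runif(12, 100, 800)) {
    got <- sort(enumerate_formulas(m, 1, ec)$formula)
    expect_equal(got, oracle_enumerate(m, 1, ec), info = paste("mass", m))
  }
})

test_that("assignment recovers generating formulae and honors the series filter", {
  pool <- sample_formula_pool(60, seed = 301, chain_length = 4)
  peaks <- data.frame(mz = pool$mass - cryodom:::PROTON_MASS,
                      intensity = 100)
  a <- assign_formulas(peaks)
  expect_equal(attr(a, "n_unassigned"), 0)
  expect_equal(sort(a$formula), sort(pool$formula))
  expect_true(all(a$series_support >= 1))
  expect_true(all(abs(a$mass_error_ppm) < 1e-3))

  # zero tolerance on noiseless data still assigns everything correctly
  a0 <- assign_formulas(peaks, tolerance_ppm = 0)
  expect_equal(sort(a0$formula), sort(pool$formula))

  # a lone peak whose candidate has no series partner stays unassigned
  lone <- data.frame(mz = pool$mass[1] - cryodom:::PROTON_MASS,
                     intensity = 100)
  al <- assign_formulas(lone, min_series_links = 1L)
  expect_equal(nrow(al), 0)
  expect_equal(attr(al, "n_unassigned"), 1)
  # with the network filter disabled it is assigned
  al0 <- assign_formulas(lone, min_series_links = 0L)
  expect_equal(al0$formula, pool$formula[1])
})

test_that("isotopologue verification removes ratio mismatches only", {
  f <- parse_formula("C20H22O10")
  mono_mz <- formula_mass(f) - cryodom:::PROTON_MASS
  good_iso <- 0.0107 * 20 * 1000       # expected 13C ratio for C20
  peaks_ok <- data.frame(mz = c(mono_mz, mono_mz + 1.0033548),
                         intensity = c(1000, good_iso))
  a <- assign_formulas(peaks_ok, min_series_links = 0L)
  a <- a[a$formula == "C20H22O10", ]
  v <- verify_isotopes(a, peaks_ok, noise_level = 1)
  expect_equal(nrow(v), 1)
  expect_true(v$isotope_checked)
  expect_equal(attr(v, "n_isotope_removed"), 0)

  # observed ratio 3x expected (deviation 2000 permil) with strong signal
  peaks_bad <- data.frame(mz = c(mono_mz, mono_mz + 1.0033548),
                          intensity = c(1000, 3 * good_iso))
  vb <- verify_isotopes(a, peaks_bad, noise_level = 1)
  expect_equal(nrow(vb), 0)
  expect_equal(attr(vb, "n_isotope_removed"), 1)

  # no isotope peak at all: retained, unchecked
  peaks_none <- data.frame(mz = mono_mz, intensity = 1000)
  vn <- verify_isotopes(a, peaks_none, noise_level = 1)
  expect_equal(nrow(vn), 1)
  expect_false(vn$isotope_checked)

  # weak isotope signal (below signal/MDL 5): check does not apply
  peaks_weak <- data.frame(mz = c(mono_mz, mono_mz + 1.0033548),
                           intensity = c(1000, 4))
  vw <- verify_isotopes(a, peaks_weak, noise_level = 1)
  expect_equal(nrow(vw), 1)
  expect_false(vw$isotope_checked)
})

test_that("blank-detected formulae are removed everywhere", {
  long <- data.frame(
    spectrum_id = c("S1", "S1", "S2", "B1"),
    sample_id = c("smpA", "smpA", "smpB", "blank"),
    formula = c("C6H10O5", "C7H12O5", "C6H10O5", "C6H10O5"),
    intensity = c(10, 5, 8, 2))
  out <- remove_blank_formulas(long, "B1")
  expect_equal(out$formula, "C7H12O5")
  expect_equal(attr(out, "n_blank_removed"), 1)
  # no overlap: unchanged (minus blank rows themselves)
  long2 <- long
  long2$formula[4] <- "C9H14O6"
  out2 <- remove_blank_formulas(long2, "B1")
  expect_equal(sort(out2$formula), c("C6H10O5", "C6H10O5", "C7H12O5"))
  expect_equal(attr(out2, "n_blank_removed"), 1)
  expect_warning(remove_blank_formulas(long, character(0)), "no blank")
})

test_that("duplicate merging enforces presence in all replicates and renormalizes", {
  long <- data.frame(
    spectrum_id = c("A_R1", "A_R1", "A_R2", "A_R2", "A_R1"),
    sample_id = "A",
    formula = c("C6H10O5", "C7H12O5", "C6H10O5", "C7H12O5", "C9H14O6"),
    intensity = c(10, 30, 20, 60, 5))
  m <- merge_duplicates(long)
  expect_s3_class(m, "fticr_matrix")
  # C9H14O6 seen in one replicate only: absent
  expect_false("C9H14O6" %in% rownames(m$intensity))
  expect_equal(m$n_dropped_duplicates, 1)
  expect_equal(sum(m$intensity[, "A"]), 1, tolerance = 1e-12)
  # identical replicate proportions: merged equals either normalized replicate
  expect_equal(unname(m$intensity[c("C6H10O5", "C7H12O5"), "A"]),
               c(0.25, 0.75), tolerance = 1e-12)
  expect_error(merge_duplicates(long[long$spectrum_id == "A_R1", ]),
               "replicate")
})

test_that("blank removal and duplicate merging commute on zero-noise data", {
  run <- zero_noise_run()
  man <- run$sim$manifest
  long <- run$mat$audit[, c("spectrum_id", "sample_id", "formula", "intensity")]
  blank_ids <- man$spectrum_id[man$is_blank]
  a <- merge_duplicates(suppressWarnings(remove_blank_formulas(long, blank_ids)))
  blank_formulas <- unique(long$formula[long$spectrum_id %in% blank_ids])
  b0 <- merge_duplicates(long[!long$spectrum_id %in% blank_ids, ])
  keep <- setdiff(rownames(b0$intensity), blank_formulas)
  b <- sweep(b0$intensity[keep, , drop = FALSE], 2,
             colSums(b0$intensity[keep, , drop = FALSE]), "/")
  expect_equal(sort(rownames(a$intensity)), sort(rownames(b)))
  expect_equal(a$intensity[rownames(b), colnames(b)], b, tolerance = 1e-12)
})

test_that("merged matrices are normalized and blank-free", {
  run <- zero_noise_run()
  expect_lt(max(abs(colSums(run$mat$intensity) - 1)), 1e-9)
  expect_false(any(run$truth$contaminants$formula %in%
                     rownames(run$mat$intensity)))
  expect_equal(run$mat$n_blank_removed, nrow(run$truth$contaminants))
})
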