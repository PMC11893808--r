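## Formula-assignment engine: from raw centroided peak lists (negative mode,
## singly charged [M-H]-) to a blank-corrected, duplicate-merged
## formula-intensity matrix.

#' Default homologous-series building blocks (Da)
#'
#' Mass differences used to link candidate formulae into homologous-series
#' networks: CH2, CO2, H2, H2O and O.
#'
#' @return named numeric vector of block masses.
#' @export
series_blocks_default <- function() {
  c(CH2 = 14.015650, CO2 = 43.989830, H2 = 2.015650,
    H2O = 18.010565, O = 15.994915)
}

## Element-count increments matching series_blocks_default()
series_block_deltas <- function() {
  list(
    CH2 = c(c = 1L, h = 2L, n = 0L, o = 0L, s = 0L, p = 0L),
    CO2 = c(c = 1L, h = 0L, n = 0L, o = 2L, s = 0L, p = 0L),
    H2  = c(c = 0L, h = 2L, n = 0L, o = 0L, s = 0L, p = 0L),
    H2O = c(c = 0L, h = 2L, n = 0L, o = 1L, s = 0L, p = 0L),
    O   = c(c = 0L, h = 0L, n = 0L, o = 1L, s = 0L, p = 0L)
  )
}

#' Estimate the per-spectrum noise level
#'
#' The noise level anchoring the method detection limit (MDL) is the median
#' intensity of the lowest-intensity decile of peaks. A user-supplied
#' constant can be passed instead wherever a `noise_level` argument exists.
#'
#' @param intensity numeric vector of peak intensities.
#' @return scalar noise level (0 for an empty spectrum).
#' @export
estimate_noise_level <- function(intensity) {
  if (!length(intensity)) return(0)
  q <- stats::quantile(intensity, 0.10, names = FALSE, type = 7)
  low <- intensity[intensity <= q]
  if (!length(low)) low <- min(intensity)
  stats::median(low)
}

#' Method-detection-limit peak filter
#'
#' Retains peaks with intensity at or above `mdl_factor` times the spectrum
#' noise level.
#'
#' @param peaks data frame with columns `mz` and `intensity`.
#' @param mdl_factor positive multiple of the noise level (default 2).
#' @param noise_level optional fixed noise level; estimated from the
#'   spectrum via [estimate_noise_level()] when `NULL`.
#' @return the retained subset of `peaks`, with the applied threshold in
#'   attribute `"mdl"`.
#' @export
mdl_filter <- function(peaks, mdl_factor = 2, noise_level = NULL) {
  if (!is.numeric(mdl_factor) || length(mdl_factor) != 1L || mdl_factor <= 0) {
    stop("mdl_factor must be a positive number")
  }
  if (!nrow(peaks)) {
    attr(peaks, "mdl") <- 0
    return(peaks)
  }
  if (is.null(noise_level)) noise_level <- estimate_noise_level(peaks$intensity)
  thr <- mdl_factor * noise_level
  out <- peaks[peaks$intensity >= thr, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mdl") <- thr
  out
}

#' Recalibrate measured m/z against known calibrant masses
#'
#' Matches calibrant ions to measured peaks within `tolerance_ppm`, keeps
#' matches whose signal-to-MDL ratio is at least `min_signal_ratio`, and
#' removes the mean signed ppm error from every peak ("mean recalibration"):
#' corrected m/z = measured m/z * (1 - mean_ppm_error * 1e-6).
#'
#' @param peaks data frame with columns `mz` and `intensity`.
#' @param calibrants numeric vector of theoretical calibrant m/z values.
#' @param tolerance_ppm match tolerance (default 0.5 ppm).
#' @param min_signal_ratio minimum calibrant signal / MDL (default 5).
#' @param mdl_factor multiple of the noise level defining the MDL.
#' @param noise_level optional fixed noise level.
#' @return `peaks` with corrected `mz`; the mean signed error that was
#'   removed is stored in attribute `"ppm_correction"`.
#' @export
recalibrate <- function(peaks, calibrants, tolerance_ppm = 0.5,
                        min_signal_ratio = 5, mdl_factor = 2,
                        noise_level = NULL) {
  stopifnot(is.numeric(calibrants), length(calibrants) >= 1L)
  if (is.null(noise_level)) noise_level <- estimate_noise_level(peaks$intensity)
  mdl <- mdl_factor * noise_level
  errs <- rep(NA_real_, length(calibrants))
  for (i in seq_along(calibrants)) {
    d_ppm <- (peaks$mz - calibrants[i]) / calibrants[i] * 1e6
    ok <- abs(d_ppm) <= tolerance_ppm &
      (mdl == 0 | peaks$intensity / max(mdl, .Machine$double.xmin) >= min_signal_ratio)
    if (any(ok)) {
      j <- which(ok)[which.min(abs(d_ppm[ok]))]
      errs[i] <- d_ppm[j]
    }
  }
  matched <- errs[!is.na(errs)]
  if (length(matched) < 3L) {
    stop("recalibration requires >= 3 matched calibrant peaks (got ",
         length(matched), "); skip recalibration explicitly for this spectrum")
  }
  corr <- mean(matched)
  out <- peaks
  out$mz <- peaks$mz * (1 - corr * 1e-6)
  attr(out, "ppm_correction") <- corr
  out
}

#' Enumerate all CHNOSP formulae matching a neutral mass
#'
#' Returns exactly the set of formulae inside the element-constraint box
#' whose theoretical neutral monoisotopic mass lies within `tolerance_ppm`
#' of `neutral_mass` and which are chemically valid (integer DBE >= 0,
#' C >= 1, H >= 1). Optional H/C and O/C screens can be enabled.
#'
#' The search solves for the hydrogen count: for every (C, N, O, S, P)
#' combination in the box there is at most one H within a sub-Da tolerance.
#'
#' @param neutral_mass neutral mass in Da (scalar).
#' @param tolerance_ppm non-negative relative tolerance.
#' @param constraints an [element_constraints()] object.
#' @param hc_range optional length-2 H/C window (e.g. `c(0.3, 2.5)`).
#' @param oc_max optional maximum O/C ratio.
#' @return data frame with element counts, `mass`, `formula` string and
#'   `error_ppm`, ordered by `|error_ppm|`.
#' @export
enumerate_formulas <- function(neutral_mass, tolerance_ppm,
                               constraints = element_constraints(),
                               hc_range = NULL, oc_max = NULL) {
  stopifnot(neutral_mass > 0, tolerance_ppm >= 0)
  ## 1e-9 Da slack keeps exact-mass matches inside a zero-width tolerance
  ## despite floating-point round-trip error
  tol_da <- neutral_mass * tolerance_ppm * 1e-6 + 1e-9
  mh <- ELEMENT_MASS[["h"]]

  cmax <- min(constraints$c[2], floor((neutral_mass + tol_da) / ELEMENT_MASS[["c"]]))
  cmin <- max(constraints$c[1], 1L)
  if (cmax < cmin) return(empty_formula_frame())
  grid <- expand.grid(
    c = cmin:cmax,
    n = constraints$n[1]:constraints$n[2],
    o = constraints$o[1]:constraints$o[2],
    s = constraints$s[1]:constraints$s[2],
    p = constraints$p[1]:constraints$p[2],
    KEEP.OUT.ATTRS = FALSE
  )
  base <- grid$c * ELEMENT_MASS[["c"]] + grid$n * ELEMENT_MASS[["n"]] +
    grid$o * ELEMENT_MASS[["o"]] + grid$s * ELEMENT_MASS[["s"]] +
    grid$p * ELEMENT_MASS[["p"]]
  h <- round((neutral_mass - base) / mh)
  mass <- base + h * mh
  keep <- h >= max(constraints$h[1], 1L) & h <= constraints$h[2] &
    abs(mass - neutral_mass) <= tol_da
  if (!any(keep)) return(empty_formula_frame())
  out <- grid[keep, , drop = FALSE]
  out$h <- as.integer(h[keep])
  out <- out[, ELEMENTS]
  out <- out[valid_formula(out, hc_range = hc_range, oc_max = oc_max), , drop = FALSE]
  if (!nrow(out)) return(empty_formula_frame())
  out$mass <- formula_mass(out)
  out$formula <- formula_string(out)
  out$error_ppm <- (out$mass - neutral_mass) / neutral_mass * 1e6
  out <- out[order(abs(out$error_ppm)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_formula_frame <- function() {
  data.frame(c = integer(), h = integer(), n = integer(), o = integer(),
             s = integer(), p = integer(), mass = numeric(),
             formula = character(), error_ppm = numeric())
}

#' Enumerate every valid formula in a constraint box
#'
#' Builds the full table of chemically valid CHNOSP formulae within the
#' constraint box and mass window, sorted by mass. Used by
#' [assign_formulas()] for fast interval lookups over many peaks.
#'
#' @inheritParams enumerate_formulas
#' @param mass_range optional mass window overriding the one stored in
#'   `constraints`.
#' @param cache reuse a previously built table for identical arguments
#'   (default TRUE).
#' @return data frame with element counts, `mass` and `formula`, sorted by
#'   `mass`.
#' @export
build_formula_table <- function(constraints = element_constraints(),
                                mass_range = NULL,
                                hc_range = c(0.3, 2.5), oc_max = 1.2,
                                cache = TRUE) {
  if (is.null(mass_range)) mass_range <- constraints$mass_range
  if (cache) {
    key <- paste(unlist(constraints), collapse = "|")
    key <- paste(key, paste(mass_range, collapse = "|"),
                 paste(hc_range, collapse = "|"),
                 paste(oc_max, collapse = "|"), sep = "||")
    hit <- .formula_table_cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  mh <- ELEMENT_MASS[["h"]]
  cmax <- min(constraints$c[2], floor(mass_range[2] / ELEMENT_MASS[["c"]]))
  cmin <- max(constraints$c[1], 1L)
  grid <- expand.grid(
    c = cmin:cmax,
    n = constraints$n[1]:constraints$n[2],
    o = constraints$o[1]:constraints$o[2],
    s = constraints$s[1]:constraints$s[2],
    p = constraints$p[1]:constraints$p[2],
    KEEP.OUT.ATTRS = FALSE
  )
  base <- grid$c * ELEMENT_MASS[["c"]] + grid$n * ELEMENT_MASS[["n"]] +
    grid$o * ELEMENT_MASS[["o"]] + grid$s * ELEMENT_MASS[["s"]] +
    grid$p * ELEMENT_MASS[["p"]]

  ## H bounds: box, mass window, DBE >= 0, optional H/C screen, and parity
  ## (integer DBE requires H = N + P mod 2).
  hmin <- pmax(max(constraints$h[1], 1L),
               ceiling((mass_range[1] - base) / mh - 1e-9))
  hmax <- pmin(constraints$h[2],
               floor((mass_range[2] - base) / mh + 1e-9),
               2L * grid$c + grid$n + grid$p + 2L)
  if (!is.null(hc_range)) {
    hmin <- pmax(hmin, ceiling(hc_range[1] * grid$c - 1e-9))
    hmax <- pmin(hmax, floor(hc_range[2] * grid$c + 1e-9))
  }
  if (!is.null(oc_max)) {
    hmax[grid$o > oc_max * grid$c] <- -1L
  }
  parity <- (grid$n + grid$p) %% 2L
  hmin <- hmin + (hmin %% 2L != parity)
  cnt <- pmax(0L, (hmax - hmin) %/% 2L + 1L)
  keep <- cnt > 0L
  grid <- grid[keep, , drop = FALSE]
  hmin <- hmin[keep]
  cnt <- cnt[keep]

  idx <- rep.int(seq_len(nrow(grid)), cnt)
  h <- rep.int(hmin, cnt) + 2L * (sequence(cnt) - 1L)
  out <- grid[idx, , drop = FALSE]
  out$h <- as.integer(h)
  out <- out[, ELEMENTS]
  out$mass <- formula_mass(out)
  out <- out[out$mass >= mass_range[1] & out$mass <= mass_range[2], , drop = FALSE]
  out <- out[order(out$mass), , drop = FALSE]
  out$formula <- formula_string(out)
  rownames(out) <- NULL
  if (cache) .formula_table_cache[[key]] <- out
  out
}

.formula_table_cache <- new.env(hash = TRUE, parent = emptyenv())

#' Assign molecular formulae to peaks via homologous-series networks
#'
#' Neutral masses are computed under the singly charged deprotonated-ion
#' convention (neutral mass = m/z + 1.00727646 Da). Candidate formulae
#' within `tolerance_ppm` are looked up in the constraint box; a candidate
#' survives only if it has at least `min_series_links` homologous-series
#' partners (CH2, CO2, H2, H2O, O element steps) among all candidate
#' formulae of the spectrum. Among surviving candidates per peak the winner
#' is chosen by `ranking`: `"parsimony"` (default) prefers the candidate
#' with the fewest heteroatoms (N+S+P) and breaks ties by smaller absolute
#' mass error — the classic CHO-preference rule, which keeps assignments
#' stable across replicate measurements because above ~500 Da the
#' constraint box contains near-isobaric heteroatom-rich alternatives
#' closer than the measurement noise; `"error"` prefers the smallest
#' absolute mass error and breaks ties by fewer heteroatoms.
#'
#' @param peaks data frame with columns `mz` and `intensity`.
#' @param constraints an [element_constraints()] object.
#' @param tolerance_ppm assignment tolerance (default 0.5 ppm).
#' @param series_blocks named vector of series block masses (informational;
#'   linking uses the corresponding element-count steps).
#' @param min_series_links minimum number of series partners (default 1;
#'   0 disables the network filter).
#' @param hc_range,oc_max candidate validity screens (set `NULL` to disable).
#' @param ranking `"parsimony"` (default) or `"error"`, see above.
#' @param formula_table optional precomputed [build_formula_table()] result.
#' @return data frame of assignments: `peak` (row index into `peaks`), `mz`,
#'   `intensity`, element counts, `formula`, `mass_error_ppm` and
#'   `series_support`; unassigned peak count in attribute `"n_unassigned"`.
#' @export
assign_formulas <- function(peaks, constraints = element_constraints(),
                            tolerance_ppm = 0.5,
                            series_blocks = series_blocks_default(),
                            min_series_links = 1L,
                            hc_range = c(0.3, 2.5), oc_max = 1.2,
                            ranking = c("parsimony", "error"),
                            formula_table = NULL) {
  ranking <- match.arg(ranking)
  if (is.null(formula_table)) {
    mr <- c(max(constraints$mass_range[1],
                min(peaks$mz) + PROTON_MASS - 1),
            min(constraints$mass_range[2],
                max(peaks$mz) + PROTON_MASS + 1))
    formula_table <- build_formula_table(constraints, mass_range = mr,
                                         hc_range = hc_range, oc_max = oc_max)
  }
  empty <- data.frame(peak = integer(), mz = numeric(), intensity = numeric(),
                      c = integer(), h = integer(), n = integer(),
                      o = integer(), s = integer(), p = integer(),
                      formula = character(), mass_error_ppm = numeric(),
                      series_support = integer())
  if (!nrow(peaks)) {
    attr(empty, "n_unassigned") <- 0L
    return(empty)
  }
  neutral <- peaks$mz + PROTON_MASS
  tol_da <- neutral * tolerance_ppm * 1e-6 + 1e-9
  lo <- findInterval(neutral - tol_da, formula_table$mass)
  hi <- findInterval(neutral + tol_da, formula_table$mass)
  n_cand <- hi - lo
  if (sum(n_cand) == 0L) {
    attr(empty, "n_unassigned") <- nrow(peaks)
    return(empty)
  }
  peak_idx <- rep.int(seq_along(neutral), n_cand)
  cand_idx <- unlist(lapply(which(n_cand > 0L), function(i) (lo[i] + 1L):hi[i]),
                     use.names = FALSE)
  cand <- formula_table[cand_idx, , drop = FALSE]
  err_ppm <- (cand$mass - neutral[peak_idx]) / neutral[peak_idx] * 1e6
  ok <- abs(cand$mass - neutral[peak_idx]) <= tol_da[peak_idx]
  peak_idx <- peak_idx[ok]
  cand <- cand[ok, , drop = FALSE]
  err_ppm <- err_ppm[ok]
  if (!nrow(cand)) {
    attr(empty, "n_unassigned") <- nrow(peaks)
    return(empty)
  }

  ## homologous-series support over the unique candidate formulae
  key <- paste(cand$c, cand$h, cand$n, cand$o, cand$s, cand$p, sep = "_")
  ukey <- unique(key)
  uc <- cand[!duplicated(key), c(ELEMENTS), drop = FALSE]
  support <- integer(length(ukey))
  for (d in series_block_deltas()) {
    for (sgn in c(1L, -1L)) {
      nb <- paste(uc$c + sgn * d[["c"]], uc$h + sgn * d[["h"]],
                  uc$n + sgn * d[["n"]], uc$o + sgn * d[["o"]],
                  uc$s + sgn * d[["s"]], uc$p + sgn * d[["p"]], sep = "_")
      support <- support + (nb %in% ukey)
    }
  }
  names(support) <- ukey
  cand_support <- support[key]
  keep <- cand_support >= min_series_links
  peak_idx <- peak_idx[keep]
  cand <- cand[keep, , drop = FALSE]
  err_ppm <- err_ppm[keep]
  cand_support <- cand_support[keep]
  if (!nrow(cand)) {
    attr(empty, "n_unassigned") <- nrow(peaks)
    return(empty)
  }

  het <- cand$n + cand$s + cand$p
  ord <- if (ranking == "parsimony") {
    order(peak_idx, het, abs(err_ppm))
  } else {
    order(peak_idx, abs(err_ppm), het)
  }
  first <- !duplicated(peak_idx[ord])
  sel <- ord[first]
  out <- data.frame(
    peak = peak_idx[sel],
    mz = peaks$mz[peak_idx[sel]],
    intensity = peaks$intensity[peak_idx[sel]],
    cand[sel, ELEMENTS, drop = FALSE],
    formula = cand$formula[sel],
    mass_error_ppm = err_ppm[sel],
    series_support = as.integer(cand_support[sel])
  )
  rownames(out) <- NULL
  attr(out, "n_unassigned") <- nrow(peaks) - nrow(out)
  out
}

#' Verify assignments against the single 13C isotopologue
#'
#' For each assignment, looks for a peak at m/z + 1.0033548 Da. When such a
#' peak exists with signal-to-MDL ratio above `min_signal_ratio`, the
#' observed isotope intensity ratio is compared with the theoretical
#' 0.0107 * C; assignments whose relative deviation exceeds
#' `ratio_tolerance_permil` are removed. Assignments without a detectable
#' isotope peak are retained.
#'
#' @param assignments result of [assign_formulas()].
#' @param peaks the peak list the assignments came from.
#' @param ratio_tolerance_permil allowed relative deviation (default 1000
#'   permil, i.e. 100 percent).
#' @param match_tolerance_ppm window for locating the isotope peak.
#' @param min_signal_ratio minimum isotope signal / MDL for the check to
#'   apply.
#' @param mdl_factor,noise_level define the MDL as in [mdl_filter()].
#' @return filtered assignments with logical column `isotope_checked`;
#'   removed count in attribute `"n_isotope_removed"`.
#' @export
verify_isotopes <- function(assignments, peaks, ratio_tolerance_permil = 1000,
                            match_tolerance_ppm = 0.5, min_signal_ratio = 5,
                            mdl_factor = 2, noise_level = NULL) {
  if (!nrow(assignments)) {
    assignments$isotope_checked <- logical(0)
    attr(assignments, "n_isotope_removed") <- 0L
    return(assignments)
  }
  if (is.null(noise_level)) noise_level <- estimate_noise_level(peaks$intensity)
  mdl <- mdl_factor * noise_level
  iso_mz <- assignments$mz + C13_DELTA
  checked <- logical(nrow(assignments))
  bad <- logical(nrow(assignments))
  ord <- order(peaks$mz)
  smz <- peaks$mz[ord]
  sint <- peaks$intensity[ord]
  for (i in seq_len(nrow(assignments))) {
    tol <- iso_mz[i] * match_tolerance_ppm * 1e-6
    j1 <- findInterval(iso_mz[i] - tol, smz)
    j2 <- findInterval(iso_mz[i] + tol, smz)
    if (j2 <= j1) next
    jj <- (j1 + 1L):j2
    j <- jj[which.max(sint[jj])]
    if (mdl > 0 && sint[j] / mdl <= min_signal_ratio) next
    checked[i] <- TRUE
    expected <- C13_ABUNDANCE * assignments$c[i]
    observed <- sint[j] / assignments$intensity[i]
    dev_permil <- abs(observed - expected) / expected * 1000
    if (dev_permil > ratio_tolerance_permil) bad[i] <- TRUE
  }
  out <- assignments[!bad, , drop = FALSE]
  out$isotope_checked <- checked[!bad]
  rownames(out) <- NULL
  attr(out, "n_isotope_removed") <- sum(bad)
  out
}

#' Remove formulae detected in blank measurements
#'
#' Any formula assigned in any blank spectrum is removed from every sample
#' ("present in the blanks" disqualifies a formula globally).
#'
#' @param long data frame with columns `spectrum_id` and `formula` (plus
#'   any others), one row per assignment.
#' @param blank_ids character vector of blank `spectrum_id`s.
#' @return `long` without blank rows and without blank-detected formulae;
#'   the number of distinct formulae removed is in attribute
#'   `"n_blank_removed"`.
#' @export
remove_blank_formulas <- function(long, blank_ids) {
  if (!length(blank_ids) || !any(long$spectrum_id %in% blank_ids)) {
    if (!length(blank_ids)) {
      warning("no blank measurements supplied; returning input unchanged")
    }
    out <- long[!(long$spectrum_id %in% blank_ids), , drop = FALSE]
    attr(out, "n_blank_removed") <- 0L
    return(out)
  }
  blank_formulas <- unique(long$formula[long$spectrum_id %in% blank_ids])
  out <- long[!(long$spectrum_id %in% blank_ids) &
                !(long$formula %in% blank_formulas), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_blank_removed") <- length(blank_formulas)
  out
}

#' Merge duplicate measurements into a formula-intensity matrix
#'
#' Each replicate spectrum is normalized to total intensity 1; a formula
#' counts as present in a sample only when detected in all replicates of
#' that sample; the merged value is the mean of the normalized replicate
#' intensities, re-normalized per sample to sum 1.
#'
#' @param long data frame with columns `spectrum_id`, `sample_id`, `formula`
#'   and `intensity`.
#' @param n_replicates expected replicate count per sample (default 2).
#' @return list of class `fticr_matrix` with elements `intensity` (matrix,
#'   formulae x samples), `n_dropped_duplicates` (formula-sample presences
#'   discarded for failing the duplicate rule).
#' @export
merge_duplicates <- function(long, n_replicates = 2L) {
  spectra <- unique(long[, c("spectrum_id", "sample_id")])
  counts <- table(spectra$sample_id)
  bad <- names(counts)[counts != n_replicates]
  if (length(bad)) {
    stop("sample(s) without the expected ", n_replicates,
         " replicate measurements: ", paste(bad, collapse = ", "))
  }
  samples <- sort(unique(long$sample_id))
  formulas <- sort(unique(long$formula))
  mat <- matrix(0, nrow = length(formulas), ncol = length(samples),
                dimnames = list(formulas, samples))
  dropped <- 0L
  for (smp in samples) {
    sub <- long[long$sample_id == smp, , drop = FALSE]
    reps <- unique(sub$spectrum_id)
    acc <- matrix(0, nrow = length(formulas), ncol = length(reps),
                  dimnames = list(formulas, reps))
    for (k in seq_along(reps)) {
      r <- sub[sub$spectrum_id == reps[k], , drop = FALSE]
      tot <- sum(r$intensity)
      if (tot <= 0) stop("replicate ", reps[k], " has zero total intensity")
      acc[r$formula, k] <- r$intensity / tot
    }
    present <- rowSums(acc > 0) == length(reps)
    dropped <- dropped + sum(rowSums(acc > 0) > 0 & !present)
    v <- rowMeans(acc)
    v[!present] <- 0
    if (sum(v) <= 0) stop("sample ", smp, " empty after duplicate merging")
    mat[, smp] <- v / sum(v)
  }
  keep <- rowSums(mat) > 0
  structure(list(intensity = mat[keep, , drop = FALSE],
                 n_dropped_duplicates = dropped),
            class = "fticr_matrix")
}

#' Run the full assignment engine on an experiment
#'
#' Applies, per spectrum: MDL filtering, optional recalibration, formula
#' assignment with homologous-series validation and optional isotopologue
#' verification; then removes blank-detected formulae and merges duplicate
#' measurements into a normalized formula-intensity matrix.
#'
#' @param peaks named list of peak tables (columns `mz`, `intensity`), one
#'   per spectrum, names matching `manifest$spectrum_id`.
#' @param manifest data frame with columns `spectrum_id`, `sample_id`,
#'   `habitat`, `pool`, `condition`, `time_days`, `replicate`, `is_blank`.
#' @param constraints an [element_constraints()] object.
#' @param tolerance_ppm assignment tolerance (default 0.5 ppm).
#' @param mdl_factor MDL multiple (default 2).
#' @param min_series_links homologous-series threshold (default 1).
#' @param hc_range,oc_max candidate validity screens.
#' @param ranking candidate ranking rule, see [assign_formulas()].
#' @param calibrants optional numeric vector of calibrant m/z values; when
#'   supplied each spectrum is recalibrated before assignment.
#' @param check_isotopes run [verify_isotopes()] per spectrum (default TRUE).
#' @param n_replicates expected replicates per sample.
#' @return object of class `fticr_matrix`: `intensity` (formulae x samples,
#'   columns sum to 1), `samples` (per-sample manifest), `audit` (per-peak
#'   assignment audit), and provenance counts (`n_blank_removed`,
#'   `n_dropped_duplicates`, `n_unassigned`, `n_isotope_removed`).
#' @export
assign_experiment <- function(peaks, manifest,
                              constraints = element_constraints(),
                              tolerance_ppm = 0.5, mdl_factor = 2,
                              min_series_links = 1L,
                              hc_range = c(0.3, 2.5), oc_max = 1.2,
                              ranking = c("parsimony", "error"),
                              calibrants = NULL, check_isotopes = TRUE,
                              n_replicates = 2L) {
  ranking <- match.arg(ranking)
  stopifnot(all(manifest$spectrum_id %in% names(peaks)))
  all_mz <- unlist(lapply(peaks[manifest$spectrum_id], function(p) range(p$mz)),
                   use.names = FALSE)
  mr <- c(max(constraints$mass_range[1], min(all_mz) + PROTON_MASS - 1),
          min(constraints$mass_range[2], max(all_mz) + PROTON_MASS + 1))
  ftab <- build_formula_table(constraints, mass_range = mr,
                              hc_range = hc_range, oc_max = oc_max)

  audits <- vector("list", nrow(manifest))
  n_unassigned <- 0L
  n_iso_removed <- 0L
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$spectrum_id[i]
    p <- mdl_filter(peaks[[sid]], mdl_factor = mdl_factor)
    noise <- attr(p, "mdl") / mdl_factor
    if (!is.null(calibrants)) {
      p <- recalibrate(p, calibrants, tolerance_ppm = tolerance_ppm,
                       mdl_factor = mdl_factor, noise_level = noise)
    }
    a <- assign_formulas(p, constraints = constraints,
                         tolerance_ppm = tolerance_ppm,
                         min_series_links = min_series_links,
                         hc_range = hc_range, oc_max = oc_max,
                         ranking = ranking, formula_table = ftab)
    n_unassigned <- n_unassigned + attr(a, "n_unassigned")
    if (check_isotopes) {
      a <- verify_isotopes(a, p, mdl_factor = mdl_factor, noise_level = noise,
                           match_tolerance_ppm = tolerance_ppm)
      n_iso_removed <- n_iso_removed + attr(a, "n_isotope_removed")
    } else {
      a$isotope_checked <- FALSE
    }
    if (nrow(a)) {
      ## a formula hit by two peaks in one spectrum keeps its strongest peak
      a <- a[order(a$formula, -a$intensity), , drop = FALSE]
      a <- a[!duplicated(a$formula), , drop = FALSE]
      a$spectrum_id <- sid
      a$sample_id <- manifest$sample_id[i]
      audits[[i]] <- a
    }
  }
  long <- do.call(rbind, audits)
  rownames(long) <- NULL

  blank_ids <- manifest$spectrum_id[manifest$is_blank]
  long2 <- if (length(blank_ids)) {
    remove_blank_formulas(long, blank_ids)
  } else {
    structure(long, n_blank_removed = 0L)
  }
  n_blank_removed <- attr(long2, "n_blank_removed")

  merged <- merge_duplicates(long2[, c("spectrum_id", "sample_id", "formula",
                                       "intensity")],
                             n_replicates = n_replicates)
  sample_tab <- unique(manifest[!manifest$is_blank,
                                c("sample_id", "habitat", "pool", "condition",
                                  "time_days")])
  sample_tab <- sample_tab[match(colnames(merged$intensity),
                                 sample_tab$sample_id), , drop = FALSE]
  rownames(sample_tab) <- NULL
  structure(list(intensity = merged$intensity,
                 samples = sample_tab,
                 audit = long,
                 n_blank_removed = n_blank_removed,
                 n_dropped_duplicates = merged$n_dropped_duplicates,
                 n_unassigned = n_unassigned,
                 n_isotope_removed = n_iso_removed),
            class = "fticr_matrix")
}

#' @export
print.fticr_matrix <- function(x, ...) {
  cat("<fticr_matrix> ", nrow(x$intensity), " formulae x ",
      ncol(x$intensity), " samples\n", sep = "")
  if (!is.null(x$n_blank_removed)) {
    cat("  blank-removed formulae: ", x$n_blank_removed,
        "; duplicate-rule drops: ", x$n_dropped_duplicates, "\n", sep = "")
  }
  invisible(x)
}
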