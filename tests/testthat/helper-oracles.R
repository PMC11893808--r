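# Independent oracles and shared fixtures.

# Exhaustive enumeration over the element box by explicit nested loops over
# N, S, P, O and C, with an explicit scan over the admissible H range per
# cell. Independent of the package's solve-and-round / sorted-table path.
oracle_enumerate <- function(neutral_mass, tolerance_ppm,
                             constraints = element_constraints(),
                             hc_range = NULL, oc_max = NULL) {
  mC <- 12; mH <- 1.00782503; mN <- 14.00307401
  mO <- 15.99491462; mS <- 31.97207069; mP <- 30.97376200
  tol <- neutral_mass * tolerance_ppm * 1e-6 + 1e-9
  hi <- neutral_mass + tol
  lo <- neutral_mass - tol
  found <- character(0)
  for (nn in constraints$n[1]:constraints$n[2]) {
    for (ss in constraints$s[1]:constraints$s[2]) {
      for (pp in constraints$p[1]:constraints$p[2]) {
        for (oo in constraints$o[1]:constraints$o[2]) {
          base <- nn * mN + ss * mS + pp * mP + oo * mO
          if (base > hi) next
          for (cc in max(1L, constraints$c[1]):constraints$c[2]) {
            m0 <- base + cc * mC
            if (m0 > hi) break
            h_lo <- max(max(1L, constraints$h[1]),
                        ceiling((lo - m0) / mH - 1e-12))
            h_hi <- min(constraints$h[2], floor((hi - m0) / mH + 1e-12))
            if (h_hi < h_lo) next
            for (hh in h_lo:h_hi) {
              m <- m0 + hh * mH
              if (m < lo || m > hi) next
              dbe <- 1 + (2 * cc - hh + nn + pp) / 2
              if (dbe < 0 || abs(dbe - round(dbe)) > 1e-9) next
              if (!is.null(hc_range) &&
                  (hh / cc < hc_range[1] || hh / cc > hc_range[2])) next
              if (!is.null(oc_max) && oo / cc > oc_max) next
              sym <- c(C = cc, H = hh, N = nn, O = oo, P = pp, S = ss)
              sym <- sym[sym > 0]
              found <- c(found, paste0(names(sym), sym, collapse = ""))
            }
          }
        }
      }
    }
  }
  sort(found)
}

# Textbook Bray-Curtis: 1 - 2*sum(min)/sum(both), explicit double loop.
oracle_bray <- function(m) {
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- 1 - 2 * sum(pmin(m[, i], m[, j])) / sum(m[, i] + m[, j])
    }
  }
  d
}

# Small complete synthetic run shared across tests (zero-noise, cached).
zero_noise_run <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    pool <- sample_formula_pool(100, seed = 101)
    truth <- planted_truth(pool, noise_cv = 0, mz_error_ppm_sd = 0,
                           dropout_fraction = 0, seed = 102)
    sim <- simulate_experiment(experiment_design(), truth, seed = 103)
    mat <- assign_experiment(sim$peaks, sim$manifest)
    labels <- classify_trajectories(mat)
    cache <<- list(pool = pool, truth = truth, sim = sim, mat = mat,
                   labels = labels)
    cache
  }
})

# Two-habitat marker fixture for ordination tests: disjoint marker formulae
# over a shared background, with per-sample abundance noise.
marker_fixture <- function(n_mark = 30, n_bg = 90, n_samples = 8, seed = 400) {
  set.seed(seed)
  fm <- sample_formula_pool(2 * n_mark + n_bg, seed = seed, chain_length = 3)
  markers_a <- fm$formula[seq_len(n_mark)]
  markers_b <- fm$formula[n_mark + seq_len(n_mark)]
  bg <- fm$formula[2 * n_mark + seq_len(n_bg)]
  base_bg <- stats::rlnorm(n_bg, 0, 0.4)
  col_for <- function(markers) {
    v <- stats::setNames(numeric(nrow(fm)), fm$formula)
    v[bg] <- base_bg * stats::rlnorm(n_bg, 0, 0.25)
    v[markers] <- stats::rlnorm(n_mark, 0.7, 0.25)
    v / sum(v)
  }
  m <- cbind(
    vapply(seq_len(n_samples), function(i) col_for(markers_a), numeric(nrow(fm))),
    vapply(seq_len(n_samples), function(i) col_for(markers_b), numeric(nrow(fm)))
  )
  colnames(m) <- c(paste0("ICE_", seq_len(n_samples)),
                   paste0("SNOW_", seq_len(n_samples)))
  list(m = m, habitats = rep(c("ICE", "SNOW"), each = n_samples),
       markers_a = markers_a, markers_b = markers_b)
}
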