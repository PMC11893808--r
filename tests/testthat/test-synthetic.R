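test_that("formula pools are distinct, valid, in-window and deterministic", {
  pool <- sample_formula_pool(60, seed = 5, chain_length = 4)
  expect_equal(nrow(pool), 60)
  expect_false(any(duplicated(pool$formula)))
  expect_true(all(pool$mass >= 100 & pool$mass <= 800))
  expect_true(all(cryodom:::valid_formula(pool, hc_range = c(0.3, 2.5),
                                          oc_max = 1.2)))
  expect_true(all(pool$c >= 1 & pool$h >= 1))
  # every chain member has at least one series partner inside its chain
  deltas <- cryodom:::series_block_deltas()
  key <- paste(pool$c, pool$h, pool$n, pool$o, pool$s, pool$p, pool$chain_id,
               sep = "_")
  has_partner <- vapply(seq_len(nrow(pool)), function(i) {
    any(vapply(deltas, function(d) {
      any(paste(pool$c[i] + c(1, -1) * d[["c"]], pool$h[i] + c(1, -1) * d[["h"]],
                pool$n[i] + c(1, -1) * d[["n"]], pool$o[i] + c(1, -1) * d[["o"]],
                pool$s[i] + c(1, -1) * d[["s"]], pool$p[i] + c(1, -1) * d[["p"]],
                pool$chain_id[i], sep = "_") %in% key)
    }, logical(1)))
  }, logical(1))
  expect_true(all(has_partner))
  # determinism
  pool2 <- sample_formula_pool(60, seed = 5, chain_length = 4)
  expect_identical(pool, pool2)

  # a constraint box of size one forces that single formula
  box1 <- element_constraints(c = c(6L, 6L), h = c(10L, 10L), o = c(5L, 5L),
                              n = c(0L, 0L), s = c(0L, 0L), p = c(0L, 0L),
                              mass_range = c(100, 800))
  expect_equal(sample_formula_pool(1, box1, seed = 1, chain_length = 1)$formula,
               "C6H10O5")
  expect_error(sample_formula_pool(2, box1, seed = 1), "cannot sample")
})

test_that("an all-refractory zero-noise experiment is constant everywhere", {
  pool <- sample_formula_pool(20, seed = 7, chain_length = 4)
  truth <- planted_truth(pool, habitats = "GIA",
                         class_fractions = c(refractory = 1.0),
                         noise_cv = 0, mz_error_ppm_sd = 0,
                         dropout_fraction = 0, n_contaminants = 0L,
                         seed = 8)
  sim <- simulate_experiment(experiment_design(habitats = "GIA"), truth,
                             seed = 9)
  P <- sim$patterns$GIA
  expect_true(all(P > 0))
  expect_equal(apply(P, 1, function(r) max(r) - min(r)), rep(0, nrow(P)),
               ignore_attr = TRUE)
})

test_that("planted extinction zeroes exactly the degraded half in the dark", {
  pool <- sample_formula_pool(40, seed = 17, chain_length = 4)
  truth <- planted_truth(
    pool, habitats = "GIA",
    class_fractions = c(hetero_degraded = 0.5, refractory = 0.5),
    dynamics = dynamics_params(frac_to_zero = 1, extinction_time = 15),
    noise_cv = 0, mz_error_ppm_sd = 0, dropout_fraction = 0,
    n_contaminants = 0L, seed = 18)
  sim <- simulate_experiment(experiment_design(habitats = "GIA"), truth,
                             seed = 19)
  asg <- truth$class_assignment
  P <- sim$patterns$GIA
  g <- sim$sample_grid$GIA
  late_dark <- g$sample_id[g$pool == "DOM" & g$condition == "DARK" &
                             g$time_days >= 15]
  hd <- asg$formula[asg$class == "hetero_degraded"]
  rf <- asg$formula[asg$class == "refractory"]
  expect_true(all(P[hd, late_dark] == 0))
  expect_true(all(P[rf, late_dark] > 0))
})

test_that("simulated experiments are deterministic and mass-honest", {
  pool <- sample_formula_pool(40, seed = 27, chain_length = 4)
  truth <- planted_truth(pool, seed = 28)
  d <- experiment_design()
  s1 <- simulate_experiment(d, truth, seed = 29)
  s2 <- simulate_experiment(d, truth, seed = 29)
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(s1$truth_table, s2$truth_table)

  # every planted presence yields a peak within 4 x ppm-sd of theory in
  # both replicates, except the deliberately dropped slots
  sd_ppm <- truth$mz_error_ppm_sd
  for (h in names(s1$patterns)) {
    P <- s1$patterns[[h]][pool$formula, , drop = FALSE]
    theo <- pool$mass - cryodom:::PROTON_MASS
    for (smp in colnames(P)) {
      present <- which(P[, smp] > 0)
      for (r in 1:2) {
        sid <- paste0(smp, "_R", r)
        dropped <- s1$dropout[s1$dropout$habitat == h &
                                s1$dropout$sample_id == smp &
                                s1$dropout$replicate == r, "formula"]
        mz <- s1$peaks[[sid]]$mz
        for (i in present) {
          if (pool$formula[i] %in% dropped) next
          dev <- min(abs(mz - theo[i]) / theo[i] * 1e6)
          expect_lt(dev, 4 * sd_ppm + 1e-6)
        }
      }
    }
    break  # one habitat suffices for the sweep
  }
})

test_that("zero-noise planted trends are monotone in the emitted patterns", {
  run <- zero_noise_run()
  truth <- run$truth
  for (h in c("GIA", "RSA")) {
    P <- run$sim$patterns[[h]]
    g <- run$sim$sample_grid[[h]]
    asg <- truth$class_assignment[truth$class_assignment$habitat == h, ]
    dark <- g$sample_id[g$pool == "DOM" &
                          g$condition %in% c("INITIAL", "DARK")]
    dark <- dark[order(g$time_days[match(dark, g$sample_id)])]
    light <- g$sample_id[g$pool == "DOM" &
                           g$condition %in% c("INITIAL", "LIGHT")]
    light <- light[order(g$time_days[match(light, g$sample_id)])]
    hd <- asg$formula[asg$class == "hetero_degraded"]
    expect_true(all(apply(P[hd, dark], 1, function(v) all(diff(v) <= 0))))
    hp <- asg$formula[asg$class == "hetero_produced"]
    expect_true(all(apply(P[hp, dark], 1, function(v) all(diff(v) >= 0))))
    pp <- asg$formula[asg$class == "photoproduced"]
    expect_true(all(apply(P[pp, light], 1, function(v) all(diff(v) >= 0))))
    expect_true(all(P[pp, dark] == 0))
  }
})

test_that("truth tables and class fractions stay consistent", {
  run <- zero_noise_run()
  tt <- run$sim$truth_table
  fr <- class_fractions_default()
  for (h in c("GIA", "RSA")) {
    cls <- table(tt$class[tt$habitat == h])
    for (k in names(fr)) {
      expect_equal(unname(cls[k]) / nrow(run$pool), unname(fr[k]),
                   tolerance = 0.05)
    }
  }
  expect_error(planted_truth(run$pool,
                             class_fractions = c(refractory = 0.7,
                                                 transferred = 0.6)),
               "sum")
  expect_error(planted_truth(run$pool,
                             class_fractions = c(bogus = 0.5)),
               "unknown class")
})
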