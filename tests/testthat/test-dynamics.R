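test_that("consistent-decrease test follows the running-minimum rule", {
  t5 <- c(0, 3, 6, 9, 15)
  r <- monotone_rule()
  d <- is_consistent_decrease(t5, c(10, 8, 5, 0, 0), r)
  expect_true(d$pass)
  expect_true(d$reached_zero)
  expect_equal(d$event_time, 9)

  # +10% backstep relative to the running minimum is not allowed
  expect_false(is_consistent_decrease(c(0, 3, 6, 9), c(10, 11, 5, 1), r)$pass)
  # constant series has no net decrease
  expect_false(is_consistent_decrease(c(0, 3, 6), c(10, 10, 10), r)$pass)
  # absent at T0: not eligible
  expect_false(is_consistent_decrease(c(0, 3, 6), c(0, 5, 1), r)$pass)
  # too few points
  expect_false(is_consistent_decrease(c(0, 3), c(10, 1), r)$pass)
  # decrease without reaching zero: event time is the last observation
  d2 <- is_consistent_decrease(t5, c(10, 8, 6, 4, 3), r)
  expect_true(d2$pass)
  expect_false(d2$reached_zero)
  expect_equal(d2$event_time, 15)
  # a transient zero that recovers is not "reached zero"
  d3 <- is_consistent_decrease(t5, c(10, 5, 0, 0.4, 0.1),
                               monotone_rule(tolerance_rel = 0.10,
                                             zero_eps = 0.05))
  expect_false(d3$reached_zero)
})

test_that("consistent-increase test mirrors the decrease rule", {
  r <- monotone_rule()
  i1 <- is_consistent_increase(c(0, 3, 6, 9), c(0, 2, 5, 9), r)
  expect_true(i1$pass)
  expect_equal(i1$max_time, 9)
  expect_false(is_consistent_increase(c(0, 3, 6), c(5, 4, 3), r)$pass)
  # small backstep below the running maximum is tolerated
  expect_true(is_consistent_increase(c(0, 3, 6, 9), c(1, 4, 3.8, 9), r)$pass)
  # large backstep is not
  expect_false(is_consistent_increase(c(0, 3, 6, 9), c(1, 4, 2, 9), r)$pass)
  # net change must exceed min_change for a present-at-T0 series
  expect_false(is_consistent_increase(c(0, 3, 6), c(10, 10.5, 11), r)$pass)
})

# hand-built matrix: one habitat, DOM only, three timepoints per condition
mini_matrix <- function(values) {
  samples <- data.frame(
    sample_id = c("H_DOM_T0", "H_DOM_L_T3", "H_DOM_L_T6", "H_DOM_L_T9",
                  "H_DOM_D_T3", "H_DOM_D_T6", "H_DOM_D_T9",
                  "H_POM_HW_T0"),
    habitat = "H", pool = c(rep("DOM", 7), "POM_HW"),
    condition = c("INITIAL", "LIGHT", "LIGHT", "LIGHT",
                  "DARK", "DARK", "DARK", "INITIAL"),
    time_days = c(0, 3, 6, 9, 3, 6, 9, 0))
  m <- matrix(unlist(values, use.names = FALSE), nrow = length(values),
              byrow = TRUE, dimnames = list(names(values), samples$sample_id))
  list(intensity = m, samples = samples)
}

test_that("dark-side labels need DOM-T0 presence and ignore light behavior", {
  mat <- mini_matrix(list(
    # T0   L3   L6   L9   D3   D6   D9  POM0
    dark_decay  = c(10, 10, 10, 10, 6, 3, 1, 0),
    both_decay  = c(10, 6, 3, 1, 6, 3, 1, 0),
    dark_rise   = c(1, 1, 1, 1, 3, 6, 10, 0),
    flat        = c(5, 5, 5, 5, 5, 5, 5, 0)))
  lab <- classify_trajectories(mat)
  lab <- lab[match(rownames(mat$intensity), lab$formula), ]
  expect_equal(lab$dark, c("HETERO_DEGRADED", "HETERO_DEGRADED",
                           "HETERO_PRODUCED", "none"))
  # decreasing in both conditions still earns the dark label ("not exclusively")
  expect_equal(lab$dark[2], "HETERO_DEGRADED")
  # but no light label, because the dark series also decreases
  expect_equal(lab$light[2], "none")
})

test_that("light-side labels enforce the light-exclusivity clause", {
  mat <- mini_matrix(list(
    photo_prod  = c(0, 2, 5, 9, 0, 0, 0, 0),
    both_rise   = c(0, 2, 5, 9, 1, 4, 8, 0),
    photo_decay = c(10, 6, 3, 1, 10, 10, 10, 0)))
  lab <- classify_trajectories(mat)
  lab <- lab[match(rownames(mat$intensity), lab$formula), ]
  expect_equal(lab$light, c("PHOTOPRODUCED", "none", "PHOTO_DEGRADED"))
  expect_equal(lab$dark, c("none", "HETERO_PRODUCED", "none"))
})

test_that("transfer needs POM-T0 membership and light-exclusive DOM presence", {
  mat <- mini_matrix(list(
    transferred = c(0, 2, 5, 9, 0, 0, 0, 7),
    leak_dark   = c(0, 2, 5, 9, 0, 3, 0, 7),
    no_pom      = c(0, 2, 5, 9, 0, 0, 0, 0)))
  lab <- classify_trajectories(mat)
  lab <- lab[match(rownames(mat$intensity), lab$formula), ]
  expect_equal(lab$transfer, c("TRANSFERRED", "none", "none"))
  expect_equal(lab$pom_extract[1], "POM_HW")
  # relaxed mode tolerates sparse dark appearances
  lab_rel <- classify_trajectories(mat, transfer_mode = "relaxed",
                                   relaxed_frac = 0.6)
  lab_rel <- lab_rel[match(rownames(mat$intensity), lab_rel$formula), ]
  expect_equal(lab_rel$transfer[2], "TRANSFERRED")
})

test_that("refractory needs continuous presence in occupied pools and no degraded label", {
  mat <- mini_matrix(list(
    always      = c(5, 5, 5, 5, 5, 5, 5, 5),
    gap         = c(5, 5, 0, 5, 5, 5, 5, 5),
    degr_slow   = c(10, 10, 10, 10, 8, 6, 4, 0),
    dom_only    = c(5, 5, 5, 5, 5, 5, 5, 0)))
  lab <- classify_trajectories(mat)
  lab <- lab[match(rownames(mat$intensity), lab$formula), ]
  expect_equal(lab$refractory,
               c("REFRACTORY", "none", "none", "REFRACTORY"))
  # the slow decayer is excluded by its degraded label, not by absence
  expect_equal(lab$dark[3], "HETERO_DEGRADED")
  expect_false(lab$dark_reached_zero[3])
})

test_that("sparse particulate timepoints restrict the refractory presence check", {
  design <- experiment_design(
    habitats = "RSA",
    pool_timepoints = list(RSA.POM_HW = c(0, 24), RSA.POM_NAOH = c(0, 24)))
  grid <- cryodom:::habitat_sample_grid(design, "RSA")
  expect_equal(sum(grid$pool == "POM_HW"), 3)  # T0 + light/dark at day 24
  pool <- sample_formula_pool(40, seed = 71, chain_length = 4)
  truth <- planted_truth(pool, habitats = "RSA", noise_cv = 0,
                         mz_error_ppm_sd = 0, dropout_fraction = 0,
                         n_contaminants = 0L, seed = 72)
  sim <- simulate_experiment(design, truth, seed = 73)
  mat <- assign_experiment(sim$peaks, sim$manifest)
  labels <- classify_trajectories(mat)
  cmp <- merge(labels, sim$truth_table, by = c("habitat", "formula"))
  expect_equal(cmp$refractory, cmp$expected_refractory)
})

test_that("label families are mutually exclusive over a full synthetic run", {
  run <- zero_noise_run()
  lab <- run$labels
  expect_false(any(lab$dark == "HETERO_PRODUCED" & lab$dark == "HETERO_DEGRADED"))
  expect_false(any(lab$light == "PHOTOPRODUCED" & lab$dark == "HETERO_PRODUCED"))
  refr <- lab$refractory == "REFRACTORY"
  expect_false(any(refr & (lab$dark == "HETERO_DEGRADED" |
                             lab$light == "PHOTO_DEGRADED")))
})

test_that("pool percentages use the stated denominators and bounds", {
  run <- zero_noise_run()
  rep <- pool_percentages(run$labels, run$mat)
  tt <- run$sim$truth_table
  for (h in c("GIA", "RSA")) {
    p <- rep[[h]]$percentages
    expect_true(all(p$percent >= 0 & p$percent <= 100))
    n_pom <- sum(tt$habitat == h &
                   tt$class %in% c("refractory", "background", "transferred"))
    expect_equal(unname(rep[[h]]$denominators["pom_t0"]), n_pom)
    expect_lte(p$n[p$process == "transferred"],
               unname(rep[[h]]$denominators["pom_t0"]))
    # zero-noise percentages equal the planted shares exactly
    expect_equal(p$percent[p$process == "transferred"],
                 100 * sum(tt$habitat == h & tt$class == "transferred") / n_pom)
  }
  # a refractory-pool summary reproduces the descriptor layout
  s <- rep$GIA$summaries$refractory
  expect_true(!is.null(s))
  expect_equal(sum(s$elemental_pct), 100)
})
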