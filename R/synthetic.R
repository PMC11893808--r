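## Synthetic incubation experiments with planted process classes.
##
## The generator emulates the field design: two habitats (glacier ice-algae
## GIA, red snow-algae RSA), three OM pools (DOM, hot-water and NaOH POM
## extracts), light/dark incubation series over 0-24 days, duplicate
## measurements, procedural blanks. Each formula carries a planted process
## class whose relative-abundance time course the downstream classifier
## should recover.

#' Experimental layout of a synthetic incubation
#'
#' @param habitats habitat codes (default GIA and RSA).
#' @param pools OM pool codes; `DOM` is the dissolved pool, `POM_HW` and
#'   `POM_NAOH` the water-soluble and water-insoluble particulate extracts.
#' @param conditions incubation conditions for timepoints after T0.
#' @param timepoints_days strictly increasing, starting at 0.
#' @param n_replicates duplicate measurements per sample (default 2).
#' @param n_blanks number of procedural blank samples (default 6).
#' @param pool_timepoints optional named list restricting the measured
#'   timepoints of a habitat/pool combination, e.g.
#'   `list(RSA.POM_HW = c(0, 24))` when intermediate particulate samples
#'   could not be analyzed.
#' @return object of class `experiment_design`.
#' @export
experiment_design <- function(habitats = c("GIA", "RSA"),
                              pools = c("DOM", "POM_HW", "POM_NAOH"),
                              conditions = c("LIGHT", "DARK"),
                              timepoints_days = c(0, 3, 6, 9, 15, 22, 24),
                              n_replicates = 2L,
                              n_blanks = 6L,
                              pool_timepoints = NULL) {
  stopifnot(length(habitats) >= 1, length(pools) >= 1)
  if (timepoints_days[1] != 0 || any(diff(timepoints_days) <= 0)) {
    stop("timepoints_days must be strictly increasing and start at 0")
  }
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (n_blanks < 0L) stop("n_blanks must be >= 0")
  structure(list(habitats = habitats, pools = pools, conditions = conditions,
                 timepoints_days = timepoints_days,
                 n_replicates = as.integer(n_replicates),
                 n_blanks = as.integer(n_blanks),
                 pool_timepoints = pool_timepoints),
            class = "experiment_design")
}

#' Default planted class fractions
#'
#' Fractions of the formula pool assigned to each process class; the
#' remainder is unclassified background. With the defaults the particulate
#' T0 pool consists of transferred, refractory and background formulae, so
#' the planted transfer share of POM-T0 is 30 percent.
#'
#' @return named numeric vector.
#' @export
class_fractions_default <- function() {
  c(transferred = 0.15, photoproduced = 0.10, photo_degraded = 0.10,
    hetero_produced = 0.10, hetero_degraded = 0.20, refractory = 0.15)
}

#' Planted intensity-dynamics parameters
#'
#' Degraded formulae deplete linearly in relative abundance, down to a
#' residual fraction `residual_frac` of their initial abundance at the end
#' of the incubation; a fraction `frac_to_zero` of each degraded class
#' depletes linearly all the way to zero, reached at `extinction_time`
#' (days). Production mirrors degradation: the total abundance lost by the
#' degraded formulae of a series is redistributed over the produced
#' formulae. This keeps per-sample total intensity constant, so planted
#' shapes survive normalization exactly, and it keeps every planted trend
#' moving at each timepoint by amounts well above duplicate-level noise —
#' the property the monotonicity classifier relies on (saturating forms
#' whose late increments vanish below measurement noise are
#' indistinguishable from constancy).
#'
#' @param residual_frac fraction of the initial abundance remaining at the
#'   final timepoint for degraded-but-surviving formulae.
#' @param frac_to_zero fraction of degraded chains depleting to zero.
#' @param extinction_time day at which those chains reach zero.
#' @return list of dynamics parameters.
#' @export
dynamics_params <- function(residual_frac = 0.1, frac_to_zero = 0.5,
                            extinction_time = 15) {
  stopifnot(residual_frac >= 0, residual_frac < 1,
            frac_to_zero >= 0, frac_to_zero <= 1, extinction_time > 0)
  list(residual_frac = residual_frac, frac_to_zero = frac_to_zero,
       extinction_time = extinction_time)
}

#' Sample a chemically plausible formula pool with homologous structure
#'
#' Formulae are drawn as homologous chains: a random valid core formula is
#' extended by repeated CH2 / CO2 / H2 / H2O / O steps, as in natural
#' organic matter where homologous series dominate. Every chain member
#' therefore has at least one series partner, which the assignment engine's
#' network filter requires; since the series blocks carry no N, S or P, a
#' whole chain shares one elemental class. All formulae are distinct,
#' chemically valid (integer DBE >= 0, C >= 1, H >= 1, H/C and O/C inside
#' the screens) and inside the constraint box and mass window.
#'
#' Two realism constraints shape the draw. First, core formulae are drawn
#' with heteroatom-dependent weights (`het_weights`) so that the pool is
#' CHO-dominated with decreasing shares of N-, S- and P-bearing formulae,
#' as in natural organic matter. Second, every member must be identifiable:
#' no other formula in the constraint box within `guard_ppm` of its mass
#' may have an equal or smaller heteroatom count, so the formula is the
#' unique parsimony winner of its own mass neighborhood under the
#' assignment engine's default ranking.
#'
#' @param n number of formulae (>= 1).
#' @param constraints an [element_constraints()] object; its `mass_range`
#'   bounds the neutral masses (default 100-800 Da for synthetic pools).
#' @param seed integer seed; identical calls are identical.
#' @param chain_length target chain size (default 5).
#' @param hc_range,oc_max plausibility screens applied to every member.
#' @param het_weights per-atom sampling weights for N, S and P in core
#'   formulae (weight = `wN^N * wS^S * wP^P`).
#' @param guard_ppm identifiability window (default 1 ppm, i.e. the 0.5 ppm
#'   assignment tolerance plus headroom for measurement error).
#' @return data frame: element counts, `mass`, `formula`, `chain_id`.
#' @export
sample_formula_pool <- function(n,
                                constraints = element_constraints(mass_range = c(100, 800)),
                                seed = 1L, chain_length = 5L,
                                hc_range = c(0.3, 2.5), oc_max = 1.2,
                                het_weights = c(n = 0.35, s = 0.10, p = 0.06),
                                guard_ppm = 1.0) {
  stopifnot(n >= 1, chain_length >= 1)
  tab <- build_formula_table(constraints, hc_range = hc_range, oc_max = oc_max)
  if (nrow(tab) < n) {
    stop("constraint box holds only ", nrow(tab),
         " valid formulae; cannot sample ", n)
  }
  tab_het <- tab$n + tab$s + tab$p
  core_w <- het_weights[["n"]]^tab$n * het_weights[["s"]]^tab$s *
    het_weights[["p"]]^tab$p
  core_cw <- cumsum(core_w)
  draw_core <- function() {
    findInterval(stats::runif(1) * core_cw[length(core_cw)], core_cw) + 1L
  }
  ## a formula is "identifiable" when no box formula within guard_ppm has an
  ## equal or smaller heteroatom count
  identifiable <- function(mass, het, self_formula) {
    w <- mass * guard_ppm * 1e-6
    j1 <- findInterval(mass - w, tab$mass)
    j2 <- findInterval(mass + w, tab$mass)
    if (j2 <= j1) return(TRUE)
    jj <- (j1 + 1L):j2
    jj <- jj[tab$formula[jj] != self_formula]
    !any(tab_het[jj] <= het)
  }
  set.seed(seed)
  sizes <- rep(chain_length, n %/% chain_length)
  rem <- n %% chain_length
  if (rem == 1L && length(sizes) && chain_length >= 2L) {
    sizes[length(sizes)] <- chain_length - 1L
    rem <- 2L
  }
  if (rem > 0L) sizes <- c(sizes, rem)

  deltas <- series_block_deltas()
  key_of <- function(f) paste(f$c, f$h, f$n, f$o, f$s, f$p, sep = "_")
  taken <- new.env(hash = TRUE, parent = emptyenv())
  in_box <- function(f) {
    f$c >= constraints$c[1] && f$c <= constraints$c[2] &&
      f$h >= constraints$h[1] && f$h <= constraints$h[2] &&
      f$n >= constraints$n[1] && f$n <= constraints$n[2] &&
      f$o >= constraints$o[1] && f$o <= constraints$o[2] &&
      f$s >= constraints$s[1] && f$s <= constraints$s[2] &&
      f$p >= constraints$p[1] && f$p <= constraints$p[2]
  }
  ok_member <- function(f) {
    m <- formula_mass(f)
    in_box(f) && m >= constraints$mass_range[1] && m <= constraints$mass_range[2] &&
      valid_formula(f, hc_range = hc_range, oc_max = oc_max) &&
      is.null(taken[[key_of(f)]]) &&
      identifiable(m, f$n + f$s + f$p, formula_string(f))
  }

  chains <- vector("list", length(sizes))
  for (ci in seq_along(sizes)) {
    size <- sizes[ci]
    chain <- NULL
    for (try in 1:50) {
      ri <- draw_core()
      core <- tab[ri, ELEMENTS]
      if (!is.null(taken[[key_of(core)]])) next
      if (!identifiable(tab$mass[ri], tab_het[ri], tab$formula[ri])) next
      members <- core
      cur_keys <- key_of(core)
      while (nrow(members) < size) {
        grown <- FALSE
        for (d in sample(deltas)) {
          for (sgn in sample(c(1L, -1L))) {
            ## extend from a random existing member
            base <- members[sample.int(nrow(members), 1L), , drop = FALSE]
            cand <- base
            for (el in ELEMENTS) cand[[el]] <- cand[[el]] + sgn * d[[el]]
            k <- key_of(cand)
            if (!(k %in% cur_keys) && ok_member(cand)) {
              members <- rbind(members, cand)
              cur_keys <- c(cur_keys, k)
              grown <- TRUE
              break
            }
          }
          if (grown) break
        }
        if (!grown) break
      }
      if (nrow(members) == size) {
        chain <- members
        break
      }
    }
    if (is.null(chain)) {
      stop("could not grow a homologous chain of size ", size,
           " inside the constraints; relax the constraint box")
    }
    for (k in key_of(chain)) taken[[k]] <- TRUE
    chain$chain_id <- ci
    chains[[ci]] <- chain
  }
  out <- do.call(rbind, chains)
  out$mass <- formula_mass(out)
  out$formula <- formula_string(out)
  rownames(out) <- NULL
  attr(out, "constraints") <- constraints
  attr(out, "hc_range") <- hc_range
  attr(out, "oc_max") <- oc_max
  out
}

#' Plant ground-truth process classes on a formula pool
#'
#' Whole homologous chains are assigned to process classes (per habitat,
#' independently), so that class members share presence patterns and keep
#' their series partners in every spectrum. Contaminant formulae are drawn
#' as separate chains, disjoint from the pool; a configurable chain subset
#' is also spiked into the samples to exercise blank removal.
#'
#' @param pool result of [sample_formula_pool()].
#' @param habitats habitat codes the classes are assigned for.
#' @param class_fractions named fractions of the pool per class (sum <= 1;
#'   remainder is unclassified background).
#' @param dynamics see [dynamics_params()].
#' @param noise_cv multiplicative lognormal intensity noise (coefficient of
#'   variation; 0 disables intensity noise).
#' @param mz_error_ppm_sd Gaussian m/z error spread in ppm (truncated at 4
#'   standard deviations; 0 disables mass error).
#' @param dropout_fraction fraction of pool formulae dropped from exactly
#'   one replicate of one sample (exercises the duplicate rule).
#' @param n_contaminants number of blank contaminant formulae.
#' @param contaminant_spike_fraction fraction of contaminant chains also
#'   spiked into real samples.
#' @param n_noise_peaks junk peaks per spectrum below the detection limit.
#' @param seed seed for class assignment and contaminant sampling.
#' @return object of class `planted_truth`.
#' @export
planted_truth <- function(pool, habitats = c("GIA", "RSA"),
                          class_fractions = class_fractions_default(),
                          dynamics = dynamics_params(),
                          noise_cv = 0.05, mz_error_ppm_sd = 0.1,
                          dropout_fraction = 0.02,
                          n_contaminants = 20L,
                          contaminant_spike_fraction = 0.5,
                          n_noise_peaks = 150L,
                          seed = 1L) {
  if (any(class_fractions < 0) || any(class_fractions > 1) ||
      sum(class_fractions) > 1 + 1e-12) {
    stop("class_fractions must lie in [0,1] and sum to at most 1")
  }
  stopifnot(noise_cv >= 0, mz_error_ppm_sd >= 0,
            dropout_fraction >= 0, dropout_fraction <= 1)
  known <- c("transferred", "photoproduced", "photo_degraded",
             "hetero_produced", "hetero_degraded", "refractory")
  if (!all(names(class_fractions) %in% known)) {
    stop("unknown class name(s): ",
         paste(setdiff(names(class_fractions), known), collapse = ", "))
  }
  set.seed(seed)
  n <- nrow(pool)
  chain_ids <- unique(pool$chain_id)
  chain_size <- table(pool$chain_id)

  assignment <- list()
  for (h in habitats) {
    ord <- sample(chain_ids)
    cls <- rep("background", length(ord))
    names(cls) <- as.character(ord)
    targets <- round(class_fractions * n)
    pos <- 1L
    for (k in names(targets)) {
      got <- 0L
      while (got < targets[[k]] && pos <= length(ord)) {
        cls[as.character(ord[pos])] <- k
        got <- got + chain_size[[as.character(ord[pos])]]
        pos <- pos + 1L
      }
    }
    cl_chain <- cls[as.character(pool$chain_id)]
    ## per-chain details
    extract <- rep(NA_character_, n)
    tchains <- unique(pool$chain_id[cl_chain == "transferred"])
    if (length(tchains)) {
      ext <- rep(c("POM_HW", "POM_NAOH"), length.out = length(tchains))
      extract[cl_chain == "transferred"] <-
        ext[match(pool$chain_id[cl_chain == "transferred"], tchains)]
    }
    to_zero <- rep(FALSE, n)
    for (k in c("photo_degraded", "hetero_degraded")) {
      kchains <- unique(pool$chain_id[cl_chain == k])
      nz <- round(dynamics$frac_to_zero * length(kchains))
      if (nz > 0) {
        zc <- sample(kchains, nz)
        to_zero[pool$chain_id %in% zc & cl_chain == k] <- TRUE
      }
    }
    assignment[[h]] <- data.frame(
      habitat = h, formula = pool$formula, chain_id = pool$chain_id,
      class = unname(cl_chain), pom_extract = extract, to_zero = to_zero,
      stringsAsFactors = FALSE
    )
  }
  class_assignment <- do.call(rbind, assignment)
  rownames(class_assignment) <- NULL

  contaminants <- NULL
  if (n_contaminants > 0) {
    constraints <- attr(pool, "constraints")
    for (try in 1:20) {
      cont <- sample_formula_pool(n_contaminants, constraints = constraints,
                                  seed = seed + 1000L + try,
                                  chain_length = min(5L, max(2L, n_contaminants)),
                                  hc_range = attr(pool, "hc_range"),
                                  oc_max = attr(pool, "oc_max"))
      if (!any(cont$formula %in% pool$formula)) {
        contaminants <- cont
        break
      }
    }
    if (is.null(contaminants)) stop("could not sample contaminants disjoint from the pool")
    cont_chains <- unique(contaminants$chain_id)
    n_spike <- round(contaminant_spike_fraction * length(cont_chains))
    spiked <- if (n_spike > 0) sample(cont_chains, n_spike) else integer(0)
    contaminants$spiked <- contaminants$chain_id %in% spiked
  }

  structure(list(pool = pool, class_assignment = class_assignment,
                 class_fractions = class_fractions, dynamics = dynamics,
                 noise_cv = noise_cv, mz_error_ppm_sd = mz_error_ppm_sd,
                 dropout_fraction = dropout_fraction,
                 contaminants = contaminants,
                 n_noise_peaks = as.integer(n_noise_peaks),
                 seed = seed),
            class = "planted_truth")
}

## Expected per-family labels implied by the planted dynamics.
expected_labels <- function(class_assignment) {
  cls <- class_assignment$class
  data.frame(
    class_assignment,
    expected_transfer = ifelse(cls == "transferred", "TRANSFERRED", "none"),
    expected_light = ifelse(cls %in% c("transferred", "photoproduced"),
                            "PHOTOPRODUCED",
                            ifelse(cls == "photo_degraded", "PHOTO_DEGRADED",
                                   "none")),
    expected_dark = ifelse(cls == "hetero_degraded", "HETERO_DEGRADED",
                           ifelse(cls == "hetero_produced", "HETERO_PRODUCED",
                                  "none")),
    expected_refractory = ifelse(cls == "refractory", "REFRACTORY", "none"),
    stringsAsFactors = FALSE
  )
}

## Sample grid of one habitat: T0 per pool plus light/dark series.
habitat_sample_grid <- function(design, habitat) {
  rows <- list()
  for (pool in design$pools) {
    key <- paste(habitat, pool, sep = ".")
    tps <- design$timepoints_days
    if (!is.null(design$pool_timepoints) && key %in% names(design$pool_timepoints)) {
      tps <- design$pool_timepoints[[key]]
      if (!0 %in% tps) stop("pool_timepoints for ", key, " must include 0")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      habitat = habitat, pool = pool, condition = "INITIAL", time_days = 0)
    for (cond in design$conditions) {
      for (t in setdiff(tps, 0)) {
        rows[[length(rows) + 1L]] <- data.frame(
          habitat = habitat, pool = pool, condition = cond, time_days = t)
      }
    }
  }
  g <- do.call(rbind, rows)
  cshort <- c(LIGHT = "L", DARK = "D", INITIAL = "I")
  g$sample_id <- ifelse(
    g$condition == "INITIAL",
    paste(g$habitat, g$pool, "T0", sep = "_"),
    paste(g$habitat, g$pool, cshort[g$condition], paste0("T", g$time_days),
          sep = "_"))
  g
}

## Relative-abundance pattern matrix (formulae x samples) for one habitat.
## Constructed so that every DOM column has the same total, which makes the
## planted shapes exact in normalized space.
habitat_patterns <- function(design, truth, habitat, base_intensity) {
  grid <- habitat_sample_grid(design, habitat)
  asg <- truth$class_assignment[truth$class_assignment$habitat == habitat, ]
  asg <- asg[match(truth$pool$formula, asg$formula), ]
  dyn <- truth$dynamics
  n <- nrow(truth$pool)
  P <- matrix(0, nrow = n, ncol = nrow(grid),
              dimnames = list(truth$pool$formula, grid$sample_id))
  cls <- asg$class
  I0 <- base_intensity
  t_end <- max(design$timepoints_days)

  ## linear depletion: survivors go to residual_frac * I0 at t_end,
  ## to-zero chains reach exactly 0 at the extinction time
  decay <- function(i0, t, to_zero, t_ext) {
    v <- outer(i0, 1 - (1 - dyn$residual_frac) * t / t_end)
    vz <- outer(i0, pmax(0, 1 - t / t_ext))
    v[to_zero, ] <- vz[to_zero, ]
    v
  }

  dom_cols <- function(cond) which(grid$pool == "DOM" & grid$condition == cond)
  t0_col <- function(pool) which(grid$pool == pool & grid$condition == "INITIAL")

  has_dom <- "DOM" %in% design$pools
  if (has_dom) {
    ic <- t0_col("DOM")
    lc <- dom_cols("LIGHT"); lt <- grid$time_days[lc]
    dc <- dom_cols("DARK"); dt <- grid$time_days[dc]

    refr <- cls == "refractory"
    P[refr, c(ic, lc, dc)] <- I0[refr]

    hd <- cls == "hetero_degraded"
    P[hd, ic] <- I0[hd]
    P[hd, lc] <- I0[hd]                      # unchanged in light
    P[hd, dc] <- decay(I0[hd], dt, asg$to_zero[hd], dyn$extinction_time)

    pd <- cls == "photo_degraded"
    P[pd, ic] <- I0[pd]
    P[pd, dc] <- I0[pd]                      # unchanged in dark
    P[pd, lc] <- decay(I0[pd], lt, asg$to_zero[pd], dyn$extinction_time)

    ## production mirrors degradation so DOM column totals stay constant
    dark_driver <- sum(I0[hd]) - colSums(P[hd, dc, drop = FALSE])
    light_driver <- sum(I0[pd]) - colSums(P[pd, lc, drop = FALSE])

    hp <- cls == "hetero_produced"
    if (any(hp)) {
      w_dark <- I0[hp] / sum(I0[hp])
      if (sum(dark_driver) == 0) dark_driver <- sum(I0[hp]) * dt / t_end
      P[hp, dc] <- outer(w_dark, dark_driver)
    }
    gain_light <- cls %in% c("photoproduced", "transferred", "hetero_produced")
    if (any(gain_light)) {
      w_light <- I0[gain_light] / sum(I0[gain_light])
      if (sum(light_driver) == 0) {
        light_driver <- sum(I0[gain_light]) * lt / t_end
      }
      P[gain_light, lc] <- outer(w_light, light_driver)
    }

    ## background: deterministic zigzag that fails every monotonicity test
    bg <- cls == "background"
    if (any(bg)) {
      nbg <- sum(bg)
      P[bg, ic] <- I0[bg]
      for (colset in list(lc, dc)) {
        nt <- length(colset)
        if (!nt) next
        ## strict up/down alternation with random phase per formula: each
        ## series fails both monotonicity tests, while the block total
        ## stays near-constant because phases mix
        up <- matrix(stats::runif(nbg * nt, 1.25, 1.6), nbg, nt)
        dn <- matrix(stats::runif(nbg * nt, 0.5, 0.8), nbg, nt)
        phase <- sample(0:1, nbg, replace = TRUE)
        odd <- outer(phase, seq_len(nt), function(p, j) (j + p) %% 2 == 1)
        zig <- ifelse(odd, up, dn)
        P[bg, colset] <- I0[bg] * zig
      }
    }
  }

  ## particulate pools: refractory and background everywhere, transferred in
  ## its extract of origin (depleting to zero by the end of the incubation)
  for (pool in intersect(c("POM_HW", "POM_NAOH"), design$pools)) {
    pc <- which(grid$pool == pool)
    pt <- grid$time_days[pc]
    refr <- cls == "refractory"
    P[refr, pc] <- I0[refr]
    bg <- cls == "background"
    if (any(bg)) {
      nbg <- sum(bg)
      up <- matrix(stats::runif(nbg * length(pc), 1.25, 1.6), nbg, length(pc))
      dn <- matrix(stats::runif(nbg * length(pc), 0.5, 0.8), nbg, length(pc))
      phase <- sample(0:1, nbg, replace = TRUE)
      odd <- outer(phase, seq_along(pc), function(p, j) (j + p) %% 2 == 1)
      zig <- ifelse(odd, up, dn)
      zig[, pt == 0] <- 1
      P[bg, pc] <- I0[bg] * zig
    }
    tr <- cls == "transferred" & asg$pom_extract == pool
    if (any(tr)) {
      frac <- pmax(0, 1 - pt / t_end)
      P[tr, pc] <- outer(I0[tr], frac)
    }
  }

  ## one randomly missing non-T0 sample per background formula (so that
  ## "always present" cannot hold for unclassified formulae)
  bg_idx <- which(cls == "background")
  non_t0 <- which(grid$time_days > 0)
  for (i in bg_idx) {
    present <- intersect(non_t0, which(P[i, ] > 0))
    if (length(present)) P[i, sample(present, 1L)] <- 0
  }

  ## rescale the background block so DOM column totals stay exactly
  ## constant (applied after the missing-sample holes are punched, so
  ## planted shapes survive per-sample normalization unchanged)
  if (has_dom && any(cls == "background")) {
    bg <- cls == "background"
    bg0 <- sum(I0[bg])
    for (j in c(dom_cols("LIGHT"), dom_cols("DARK"))) {
      s <- sum(P[bg, j])
      if (s > 0) P[bg, j] <- P[bg, j] * (bg0 / s)
    }
  }

  ## spiked contaminants: constant presence in every habitat sample
  if (!is.null(truth$contaminants) && any(truth$contaminants$spiked)) {
    sp <- truth$contaminants[truth$contaminants$spiked, ]
    spI <- stats::rlnorm(nrow(sp), meanlog = 0, sdlog = 0.3)
    SP <- matrix(spI, nrow = nrow(sp), ncol = ncol(P),
                 dimnames = list(sp$formula, colnames(P)))
    P <- rbind(P, SP)
  }
  list(pattern = P, grid = grid)
}

#' Simulate a complete synthetic incubation experiment
#'
#' Emits per-spectrum peak tables (measured m/z of the deprotonated ions
#' plus truncated-Gaussian ppm error, intensities with multiplicative
#' lognormal noise and sub-MDL junk peaks), a sample manifest, and a truth
#' table with the planted class and the per-family labels it implies.
#'
#' @param design an [experiment_design()].
#' @param truth a [planted_truth()].
#' @param seed integer seed controlling every random draw.
#' @return object of class `dom_simulation`: `peaks` (named list of peak
#'   tables), `manifest`, `truth_table`, `patterns` (per habitat planted
#'   relative abundances), `design`, `truth`, `seed`.
#' @export
simulate_experiment <- function(design, truth, seed = 1L) {
  stopifnot(inherits(design, "experiment_design"), inherits(truth, "planted_truth"))
  if (!nrow(truth$pool)) stop("empty formula pool")
  set.seed(seed)
  habitats <- unique(truth$class_assignment$habitat)

  base_intensity <- stats::rlnorm(nrow(truth$pool), meanlog = 0, sdlog = 0.8)

  pats <- list()
  manifest <- list()
  for (h in habitats) {
    hp <- habitat_patterns(design, truth, h, base_intensity)
    pats[[h]] <- hp
    g <- hp$grid
    for (r in seq_len(design$n_replicates)) {
      m <- g
      m$replicate <- r
      m$spectrum_id <- paste0(g$sample_id, "_R", r)
      m$is_blank <- FALSE
      manifest[[length(manifest) + 1L]] <- m
    }
  }
  for (b in seq_len(design$n_blanks)) {
    for (r in seq_len(design$n_replicates)) {
      manifest[[length(manifest) + 1L]] <- data.frame(
        habitat = NA_character_, pool = "BLANK", condition = "BLANK",
        time_days = NA_real_, sample_id = paste0("BLANK_", b),
        replicate = r, spectrum_id = paste0("BLANK_", b, "_R", r),
        is_blank = TRUE)
    }
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL

  ## dropout: a fraction of pool formulae lose their peak in exactly one
  ## replicate of one uniformly chosen sample slot, emulating sporadic
  ## detection failure (a no-op when the formula is absent there anyway)
  dropout <- list()
  for (h in habitats) {
    P <- pats[[h]]$pattern
    nf <- nrow(truth$pool)
    ndrop <- floor(truth$dropout_fraction * nf)
    if (ndrop > 0) {
      picks <- sample.int(nf, ndrop)
      for (i in picks) {
        col <- sample.int(ncol(P), 1L)
        if (P[i, col] <= 0) next
        dropout[[length(dropout) + 1L]] <- data.frame(
          habitat = h, formula = rownames(P)[i],
          sample_id = colnames(P)[col],
          replicate = sample.int(design$n_replicates, 1L))
      }
    }
  }
  dropout <- if (length(dropout)) do.call(rbind, dropout) else
    data.frame(habitat = character(), formula = character(),
               sample_id = character(), replicate = integer())

  ## global scale and noise model
  scale <- 1e7
  sdlog <- if (truth$noise_cv > 0) sqrt(log(1 + truth$noise_cv^2)) else 0
  minpos <- min(unlist(lapply(pats, function(x) {
    v <- x$pattern[seq_len(nrow(truth$pool)), , drop = FALSE]
    v[v > 0]
  })))
  pool_mz <- truth$pool$mass - PROTON_MASS
  cont_mz <- if (!is.null(truth$contaminants)) truth$contaminants$mass - PROTON_MASS
  mass_range <- attr(truth$pool, "constraints")$mass_range

  noisy_mz <- function(mz_theo) {
    if (truth$mz_error_ppm_sd == 0) return(mz_theo)
    z <- stats::rnorm(length(mz_theo))
    z <- pmin(pmax(z, -4), 4)
    mz_theo * (1 + z * truth$mz_error_ppm_sd * 1e-6)
  }
  noisy_int <- function(v) {
    if (sdlog == 0) return(v)
    v * stats::rlnorm(length(v), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  junk_peaks <- function(n) {
    if (n <= 0) return(NULL)
    data.frame(mz = stats::runif(n, mass_range[1], mass_range[2]) - PROTON_MASS,
               intensity = stats::runif(n, 0.05, 0.45) * minpos * scale)
  }

  peaks <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$spectrum_id[i]
    if (manifest$is_blank[i]) {
      tab <- NULL
      if (!is.null(truth$contaminants)) {
        ci <- stats::rlnorm(nrow(truth$contaminants), 0, 0.3)
        tab <- data.frame(mz = noisy_mz(cont_mz),
                          intensity = noisy_int(ci * scale))
      }
      tab <- rbind(tab, junk_peaks(truth$n_noise_peaks))
    } else {
      h <- manifest$habitat[i]
      P <- pats[[h]]$pattern
      v <- P[, manifest$sample_id[i]]
      rows_pool <- seq_len(nrow(truth$pool))
      mzs <- c(pool_mz, if (nrow(P) > nrow(truth$pool))
        truth$contaminants$mass[truth$contaminants$spiked] - PROTON_MASS)
      dr <- dropout[dropout$habitat == h &
                      dropout$sample_id == manifest$sample_id[i] &
                      dropout$replicate == manifest$replicate[i], ]
      if (nrow(dr)) v[match(dr$formula, rownames(P))] <- 0
      present <- v > 0
      tab <- data.frame(mz = noisy_mz(mzs[present]),
                        intensity = noisy_int(v[present] * scale))
      tab <- rbind(tab, junk_peaks(truth$n_noise_peaks))
    }
    tab <- tab[order(tab$mz), , drop = FALSE]
    rownames(tab) <- NULL
    peaks[[sid]] <- tab
  }

  truth_table <- expected_labels(truth$class_assignment)
  structure(list(peaks = peaks, manifest = manifest,
                 truth_table = truth_table,
                 patterns = lapply(pats, `[[`, "pattern"),
                 sample_grid = lapply(pats, `[[`, "grid"),
                 dropout = dropout,
                 design = design, truth = truth, seed = seed),
            class = "dom_simulation")
}

#' @export
print.dom_simulation <- function(x, ...) {
  cat("<dom_simulation> ", length(x$peaks), " spectra, ",
      nrow(x$truth$pool), " pool formulae, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write a simulated experiment to delimited text files
#'
#' One `<spectrum_id>.tsv` peak table per spectrum (columns `mz`,
#' `intensity`), plus `manifest.tsv` and `truth.tsv`.
#'
#' @param sim a `dom_simulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(sim$peaks)) {
    utils::write.table(sim$peaks[[sid]], file.path(dir, paste0(sid, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(sim$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth_table, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read peak tables and manifest written by [write_simulation()]
#'
#' @param dir directory containing `manifest.tsv` and per-spectrum tables.
#' @return list with `peaks` and `manifest` as accepted by
#'   [assign_experiment()].
#' @export
read_peak_tables <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  peaks <- lapply(manifest$spectrum_id, function(sid) {
    utils::read.table(file.path(dir, paste0(sid, ".tsv")),
                      header = TRUE, sep = "\t")
  })
  names(peaks) <- manifest$spectrum_id
  list(peaks = peaks, manifest = manifest)
}
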