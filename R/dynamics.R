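## Classification of per-formula incubation time courses into process pools:
## POM-to-DOM transfer under light, photoproduction, photodegradation,
## heterotrophic production/degradation in the dark, and refractory OM.

#' Monotone-trend rule parameters
#'
#' Operationalizes "consistent decrease/increase" of relative abundance:
#' every consecutive step must move in the trend direction or back-step by
#' less than `tolerance_rel` relative to the running extremum, and the net
#' change over the series must exceed `min_change` (relative to the initial
#' value), which separates genuine trends from duplicate-level noise.
#'
#' @param tolerance_rel allowed relative back-step (default 0.10).
#' @param min_points minimum observed timepoints (default 3).
#' @param zero_eps intensity at or below this is treated as absent
#'   (default 0).
#' @param min_change minimum net relative change (default 0.2).
#' @return object of class `monotone_rule`.
#' @export
monotone_rule <- function(tolerance_rel = 0.10, min_points = 3L,
                          zero_eps = 0, min_change = 0.2) {
  stopifnot(tolerance_rel >= 0, tolerance_rel < 1, min_points >= 2,
            zero_eps >= 0, min_change >= 0)
  structure(list(tolerance_rel = tolerance_rel,
                 min_points = as.integer(min_points),
                 zero_eps = zero_eps, min_change = min_change),
            class = "monotone_rule")
}

#' Test a time series for a consistent decrease
#'
#' A series passes when it starts present (intensity above `zero_eps` at
#' T0), every consecutive step decreases or back-steps by less than
#' `tolerance_rel` relative to the running minimum, and the final value lies
#' below `initial * (1 - min_change)`. `reached_zero` is true when the
#' series hits `zero_eps` and stays there; `event_time` is the first such
#' time (otherwise the last observed time).
#'
#' @param times numeric vector of observation times (days), increasing.
#' @param values intensities at those times.
#' @param rule a [monotone_rule()].
#' @return list with `pass`, `reached_zero`, `event_time`.
#' @export
is_consistent_decrease <- function(times, values, rule = monotone_rule()) {
  stopifnot(length(times) == length(values))
  fail <- list(pass = FALSE, reached_zero = FALSE, event_time = NA_real_)
  if (length(values) < rule$min_points) return(fail)
  if (values[1] <= rule$zero_eps) return(fail)
  runmin <- values[1]
  for (i in 2:length(values)) {
    ok <- values[i] < values[i - 1] ||
      values[i] <= runmin ||
      (runmin > 0 && (values[i] - runmin) / runmin < rule$tolerance_rel)
    if (!ok) return(fail)
    runmin <- min(runmin, values[i])
  }
  net <- values[length(values)] < values[1] * (1 - rule$min_change)
  if (!net) return(fail)
  zero <- values <= rule$zero_eps
  reached <- FALSE
  event_time <- times[length(times)]
  if (any(zero)) {
    first0 <- which(zero)[1]
    if (all(zero[first0:length(zero)])) {
      reached <- TRUE
      event_time <- times[first0]
    }
  }
  list(pass = TRUE, reached_zero = reached, event_time = event_time)
}

#' Test a time series for a consistent increase
#'
#' Mirror of [is_consistent_decrease()]: every step increases or back-steps
#' by less than `tolerance_rel` relative to the running maximum, and the
#' final value exceeds `initial * (1 + min_change)` (a series starting at
#' absence passes with any positive final value). `max_time` is the time of
#' the maximum intensity.
#'
#' @inheritParams is_consistent_decrease
#' @return list with `pass`, `max_time`.
#' @export
is_consistent_increase <- function(times, values, rule = monotone_rule()) {
  stopifnot(length(times) == length(values))
  fail <- list(pass = FALSE, max_time = NA_real_)
  if (length(values) < rule$min_points) return(fail)
  runmax <- values[1]
  for (i in 2:length(values)) {
    ok <- values[i] > values[i - 1] ||
      values[i] >= runmax ||
      (runmax > 0 && (runmax - values[i]) / runmax < rule$tolerance_rel)
    if (!ok) return(fail)
    runmax <- max(runmax, values[i])
  }
  net <- if (values[1] <= rule$zero_eps) {
    values[length(values)] > rule$zero_eps
  } else {
    values[length(values)] > values[1] * (1 + rule$min_change)
  }
  if (!net) return(fail)
  list(pass = TRUE, max_time = times[which.max(values)])
}

## Ordered sample columns of one habitat/pool/condition series, T0 first.
series_columns <- function(samples, habitat, pool, condition) {
  t0 <- samples$sample_id[samples$habitat == habitat & samples$pool == pool &
                            samples$condition == "INITIAL"]
  rest <- samples[samples$habitat == habitat & samples$pool == pool &
                    samples$condition == condition, ]
  rest <- rest[order(rest$time_days), ]
  list(ids = c(t0, rest$sample_id),
       times = c(0, rest$time_days))
}

#' Classify every formula's time course into process pools
#'
#' Applies four independent decision families per habitat:
#' \itemize{
#'   \item dark: `HETERO_DEGRADED` when the dark DOM series passes the
#'     consistent-decrease test (which requires DOM-T0 presence);
#'     `HETERO_PRODUCED` when it passes the consistent-increase test.
#'     Light-side behavior does not veto these labels.
#'   \item light: `PHOTOPRODUCED` when the light DOM series increases
#'     consistently and the dark series does not; `PHOTO_DEGRADED` when the
#'     light series decreases consistently and the dark series does not.
#'   \item transfer: `TRANSFERRED` when the formula is in a particulate
#'     extract at T0, appears in DOM under light at some t > 0, and (strict
#'     mode) never appears in DOM in the dark at t > 0; the extract of
#'     origin is recorded. Relaxed mode tolerates dark presence in up to
#'     `1 - relaxed_frac` of the dark timepoints.
#'   \item refractory: `REFRACTORY` when the formula is present in every
#'     measured sample of every pool it occupies at T0 and carries no
#'     degraded label from either family.
#' }
#'
#' @param mat an `fticr_matrix` from [assign_experiment()] (needs the
#'   `samples` table) or a list with `intensity` and `samples`.
#' @param rule a [monotone_rule()].
#' @param transfer_mode `"strict"` (default) or `"relaxed"`.
#' @param relaxed_frac minimum fraction of dark timepoints without the
#'   formula for relaxed transfer (default 0.8).
#' @return data frame with one row per (habitat, formula): columns
#'   `habitat`, `formula`, `transfer`, `pom_extract`, `light`, `dark`,
#'   `refractory`, `dark_reached_zero`, `dark_event_time`,
#'   `light_reached_zero`, `light_event_time`.
#' @export
classify_trajectories <- function(mat, rule = monotone_rule(),
                                  transfer_mode = c("strict", "relaxed"),
                                  relaxed_frac = 0.8) {
  transfer_mode <- match.arg(transfer_mode)
  m <- mat$intensity
  samples <- mat$samples
  out <- list()
  for (h in unique(samples$habitat)) {
    hs <- samples[samples$habitat == h, ]
    hm <- m[, hs$sample_id, drop = FALSE]
    formulas <- rownames(hm)[rowSums(hm > rule$zero_eps) > 0]
    light <- series_columns(hs, h, "DOM", "LIGHT")
    dark <- series_columns(hs, h, "DOM", "DARK")
    has_dom <- length(light$ids) > 1 && length(dark$ids) > 1

    pom_pools <- grep("^POM", unique(hs$pool), value = TRUE)
    pom_t0_ids <- hs$sample_id[hs$pool %in% pom_pools & hs$condition == "INITIAL"]

    res <- data.frame(habitat = h, formula = formulas,
                      transfer = "none", pom_extract = NA_character_,
                      light = "none", dark = "none", refractory = "none",
                      dark_reached_zero = NA, dark_event_time = NA_real_,
                      light_reached_zero = NA, light_event_time = NA_real_,
                      stringsAsFactors = FALSE)
    for (k in seq_along(formulas)) {
      f <- formulas[k]
      degraded <- FALSE
      inc_d <- dec_d <- list(pass = FALSE)
      if (has_dom) {
        lv <- hm[f, light$ids]
        dv <- hm[f, dark$ids]
        dec_d <- is_consistent_decrease(dark$times, dv, rule)
        inc_d <- is_consistent_increase(dark$times, dv, rule)
        if (dec_d$pass) {
          res$dark[k] <- "HETERO_DEGRADED"
          res$dark_reached_zero[k] <- dec_d$reached_zero
          res$dark_event_time[k] <- dec_d$event_time
          degraded <- TRUE
        } else if (inc_d$pass) {
          res$dark[k] <- "HETERO_PRODUCED"
          res$dark_event_time[k] <- inc_d$max_time
        }
        inc_l <- is_consistent_increase(light$times, lv, rule)
        dec_l <- is_consistent_decrease(light$times, lv, rule)
        if (inc_l$pass && !inc_d$pass) {
          res$light[k] <- "PHOTOPRODUCED"
          res$light_event_time[k] <- inc_l$max_time
        } else if (dec_l$pass && !dec_d$pass) {
          res$light[k] <- "PHOTO_DEGRADED"
          res$light_reached_zero[k] <- dec_l$reached_zero
          res$light_event_time[k] <- dec_l$event_time
          degraded <- TRUE
        }

        ## transfer: POM-T0 membership, light-exclusive appearance in DOM
        in_pom_t0 <- length(pom_t0_ids) &&
          any(hm[f, pom_t0_ids] > rule$zero_eps)
        if (in_pom_t0) {
          lt <- lv[-1]
          dt <- dv[-1]
          in_light <- any(lt > rule$zero_eps)
          dark_ok <- if (transfer_mode == "strict") {
            all(dt <= rule$zero_eps)
          } else {
            mean(dt <= rule$zero_eps) >= relaxed_frac
          }
          if (in_light && dark_ok) {
            res$transfer[k] <- "TRANSFERRED"
            ext <- pom_pools[vapply(pom_pools, function(pp) {
              id <- hs$sample_id[hs$pool == pp & hs$condition == "INITIAL"]
              length(id) && any(hm[f, id] > rule$zero_eps)
            }, logical(1))]
            res$pom_extract[k] <- paste(ext, collapse = "+")
          }
        }
      }

      ## refractory: always present in the pools occupied at T0, not degraded
      occupied <- Filter(function(pp) {
        id <- hs$sample_id[hs$pool == pp & hs$condition == "INITIAL"]
        length(id) && any(hm[f, id] > rule$zero_eps)
      }, unique(hs$pool))
      if (length(occupied) && !degraded) {
        ids <- hs$sample_id[hs$pool %in% occupied]
        if (all(hm[f, ids] > rule$zero_eps)) res$refractory[k] <- "REFRACTORY"
      }
    }
    out[[h]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Process-pool percentages and descriptor summaries
#'
#' Transferred formulae are expressed relative to the number of formulae in
#' the particulate T0 pool; produced and degraded formulae relative to the
#' DOM-T0 pool; refractory formulae as count and share of all formulae of
#' the habitat. Each process pool also receives an intensity-weighted
#' descriptor summary ([weighted_summary()]) evaluated in a reference
#' sample (DOM-T0 for degraded and refractory pools, the last light or dark
#' timepoint for photoproduced/transferred and heterotrophically produced
#' pools, the extract T0 for transferred formulae).
#'
#' @param labels result of [classify_trajectories()].
#' @param mat the `fticr_matrix` the labels were computed from.
#' @param zero_eps presence threshold (must match the rule used).
#' @param windows category windows for the summaries.
#' @return list per habitat: `denominators`, `percentages` (data frame) and
#'   `summaries` (named list of [weighted_summary()] outputs).
#' @export
pool_percentages <- function(labels, mat, zero_eps = 0,
                             windows = category_windows()) {
  m <- mat$intensity
  samples <- mat$samples
  out <- list()
  for (h in unique(labels$habitat)) {
    hs <- samples[samples$habitat == h, ]
    hl <- labels[labels$habitat == h, ]
    dom_t0 <- hs$sample_id[hs$pool == "DOM" & hs$condition == "INITIAL"]
    pom_pools <- grep("^POM", unique(hs$pool), value = TRUE)
    pom_t0 <- hs$sample_id[hs$pool %in% pom_pools & hs$condition == "INITIAL"]
    n_dom_t0 <- if (length(dom_t0)) sum(m[, dom_t0] > zero_eps) else 0L
    n_pom_t0 <- if (length(pom_t0)) {
      sum(rowSums(m[, pom_t0, drop = FALSE] > zero_eps) > 0)
    } else 0L
    n_habitat <- sum(rowSums(m[, hs$sample_id, drop = FALSE] > zero_eps) > 0)

    sets <- list(
      transferred = hl$formula[hl$transfer == "TRANSFERRED"],
      photoproduced = hl$formula[hl$light == "PHOTOPRODUCED"],
      photo_degraded = hl$formula[hl$light == "PHOTO_DEGRADED"],
      hetero_produced = hl$formula[hl$dark == "HETERO_PRODUCED"],
      hetero_degraded = hl$formula[hl$dark == "HETERO_DEGRADED"],
      refractory = hl$formula[hl$refractory == "REFRACTORY"]
    )
    denom <- c(transferred = n_pom_t0, photoproduced = n_dom_t0,
               photo_degraded = n_dom_t0, hetero_produced = n_dom_t0,
               hetero_degraded = n_dom_t0, refractory = n_habitat)
    if (any(denom == 0)) {
      stop("zero denominator for habitat ", h,
           " (missing DOM-T0, POM-T0 or habitat formulae)")
    }
    pct <- data.frame(
      process = names(sets),
      n = vapply(sets, length, integer(1)),
      denominator = denom[names(sets)],
      percent = 100 * vapply(sets, length, integer(1)) / denom[names(sets)],
      row.names = NULL
    )

    last_t <- max(hs$time_days, na.rm = TRUE)
    ref_sample <- c(
      transferred = hs$sample_id[hs$pool == "DOM" & hs$condition == "LIGHT" &
                                   hs$time_days == last_t][1],
      photoproduced = hs$sample_id[hs$pool == "DOM" & hs$condition == "LIGHT" &
                                     hs$time_days == last_t][1],
      photo_degraded = dom_t0[1],
      hetero_produced = hs$sample_id[hs$pool == "DOM" & hs$condition == "DARK" &
                                       hs$time_days == last_t][1],
      hetero_degraded = dom_t0[1],
      refractory = dom_t0[1]
    )
    summaries <- list()
    for (k in names(sets)) {
      s <- intersect(sets[[k]], rownames(m))
      s <- s[m[s, ref_sample[[k]]] > 0]
      summaries[[k]] <- if (length(s)) {
        weighted_summary(mat, s, ref_sample[[k]], windows = windows)
      } else NULL
    }
    out[[h]] <- list(denominators = c(pom_t0 = n_pom_t0, dom_t0 = n_dom_t0,
                                      habitat = n_habitat),
                     percentages = pct, summaries = summaries)
  }
  out
}
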