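## End-to-end orchestration: simulate (or read) -> assign -> describe ->
## classify -> ordinate, with all artifacts written as delimited text plus a
## machine-readable run manifest.

#' Default pipeline configuration
#'
#' @param seed global seed.
#' @param n_formulas pool size for simulated experiments.
#' @param noise_cv,mz_error_ppm_sd,dropout_fraction noise model passed to
#'   [planted_truth()].
#' @param input_dir optional directory of measured peak tables (written by
#'   [write_simulation()] or following the same layout); when `NULL` a
#'   synthetic experiment is generated.
#' @param output_dir where artifacts are written.
#' @return nested configuration list understood by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L, n_formulas = 1000L, noise_cv = 0.05,
                            mz_error_ppm_sd = 0.1, dropout_fraction = 0.02,
                            input_dir = NULL, output_dir = tempfile("cryodom_")) {
  list(
    seed = seed,
    input_dir = input_dir,
    output_dir = output_dir,
    simulate = list(n_formulas = n_formulas, noise_cv = noise_cv,
                    mz_error_ppm_sd = mz_error_ppm_sd,
                    dropout_fraction = dropout_fraction),
    design = list(habitats = c("GIA", "RSA"),
                  pools = c("DOM", "POM_HW", "POM_NAOH"),
                  conditions = c("LIGHT", "DARK"),
                  timepoints_days = c(0, 3, 6, 9, 15, 22, 24),
                  n_replicates = 2L, n_blanks = 6L),
    engine = list(tolerance_ppm = 0.5, mdl_factor = 2, min_series_links = 1L,
                  hc_range = c(0.3, 2.5), oc_max = 1.2,
                  mass_range = c(100, 1000), check_isotopes = TRUE),
    rules = list(tolerance_rel = 0.10, min_points = 3L, zero_eps = 0,
                 min_change = 0.2, transfer_mode = "strict"),
    ordination = list(k = 2, n_restarts = 20L, threshold = 0.45)
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Unspecified fields fall back to [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_lists(pipeline_config(), user)
}

merge_lists <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

## 31-bit polynomial hash of the serialized configuration, so every artifact
## can declare which configuration produced it. Run locations (input/output
## directories) are excluded: they do not affect the analysis.
config_hash <- function(config) {
  config$output_dir <- NULL
  config$input_dir <- NULL
  txt <- yaml::as.yaml(config)
  bytes <- utf8ToInt(txt)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_artifact <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(paste0("# config_hash=", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate a synthetic experiment (or read peak tables), assign
#' formulae, compute descriptors, classify time courses, compute pool
#' percentages and run the NMDS ordination. Artifacts written to the output
#' directory: `intensity_matrix.tsv`, `assignment_audit.tsv`,
#' `descriptors.tsv`, `trajectory_labels.tsv`, `pool_report.tsv`,
#' `nmds_points.tsv`, `nmds_loadings.tsv` and `run_manifest.json`. Every
#' table header declares the configuration hash.
#'
#' @param config configuration list (see [pipeline_config()]) or path to a
#'   YAML file.
#' @return invisible list with all stage results (`sim`, `mat`,
#'   `descriptors`, `labels`, `report`, `ordination`, `config_hash`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  hash <- config_hash(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  design <- experiment_design(
    habitats = config$design$habitats, pools = config$design$pools,
    conditions = config$design$conditions,
    timepoints_days = config$design$timepoints_days,
    n_replicates = config$design$n_replicates,
    n_blanks = config$design$n_blanks,
    pool_timepoints = config$design$pool_timepoints)

  sim <- NULL
  if (!is.null(config$input_dir)) {
    inp <- read_peak_tables(config$input_dir)
    peaks <- inp$peaks
    manifest <- inp$manifest
  } else {
    pool <- sample_formula_pool(
      config$simulate$n_formulas,
      constraints = element_constraints(mass_range = c(100, 800)),
      seed = config$seed)
    truth <- planted_truth(
      pool, habitats = design$habitats,
      noise_cv = config$simulate$noise_cv,
      mz_error_ppm_sd = config$simulate$mz_error_ppm_sd,
      dropout_fraction = config$simulate$dropout_fraction,
      seed = config$seed)
    sim <- simulate_experiment(design, truth, seed = config$seed)
    peaks <- sim$peaks
    manifest <- sim$manifest
  }

  reps <- table(manifest$sample_id)
  if (any(reps != design$n_replicates)) {
    stop("manifest replicate count does not match the configured ",
         design$n_replicates, " replicates per sample")
  }

  mat <- assign_experiment(
    peaks, manifest,
    constraints = element_constraints(mass_range = config$engine$mass_range),
    tolerance_ppm = config$engine$tolerance_ppm,
    mdl_factor = config$engine$mdl_factor,
    min_series_links = config$engine$min_series_links,
    hc_range = config$engine$hc_range, oc_max = config$engine$oc_max,
    check_isotopes = config$engine$check_isotopes,
    n_replicates = design$n_replicates)

  f <- parse_formula(rownames(mat$intensity))
  desc <- compute_descriptors(f)
  cats <- classify_category(desc, f)
  desc_tab <- cbind(formula = rownames(mat$intensity), desc, cats)

  rule <- monotone_rule(tolerance_rel = config$rules$tolerance_rel,
                        min_points = config$rules$min_points,
                        zero_eps = config$rules$zero_eps,
                        min_change = config$rules$min_change)
  labels <- classify_trajectories(mat, rule,
                                  transfer_mode = config$rules$transfer_mode)
  report <- pool_percentages(labels, mat, zero_eps = config$rules$zero_eps)

  ord <- nmds(mat, k = config$ordination$k, seed = config$seed,
              n_restarts = config$ordination$n_restarts)

  ## artifacts
  imat <- data.frame(formula = rownames(mat$intensity), mat$intensity,
                     check.names = FALSE)
  write_artifact(imat, file.path(out_dir, "intensity_matrix.tsv"), hash)
  write_artifact(mat$audit, file.path(out_dir, "assignment_audit.tsv"), hash)
  write_artifact(desc_tab, file.path(out_dir, "descriptors.tsv"), hash)
  write_artifact(labels, file.path(out_dir, "trajectory_labels.tsv"), hash)
  pct <- do.call(rbind, lapply(names(report), function(h) {
    cbind(habitat = h, report[[h]]$percentages)
  }))
  write_artifact(pct, file.path(out_dir, "pool_report.tsv"), hash)
  write_artifact(data.frame(sample_id = rownames(ord$points), ord$points),
                 file.path(out_dir, "nmds_points.tsv"), hash)
  write_artifact(data.frame(formula = rownames(ord$loadings), ord$loadings),
                 file.path(out_dir, "nmds_loadings.tsv"), hash)
  run_manifest <- list(
    config = config, config_hash = hash, seed = config$seed,
    package_version = as.character(utils::packageVersion("cryodom")),
    n_formulae = nrow(mat$intensity), n_samples = ncol(mat$intensity),
    n_blank_removed = mat$n_blank_removed,
    n_dropped_duplicates = mat$n_dropped_duplicates,
    n_unassigned = mat$n_unassigned,
    nmds_stress = ord$stress)
  jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  message("pipeline complete: ", nrow(mat$intensity), " formulae x ",
          ncol(mat$intensity), " samples; artifacts in ", out_dir)
  invisible(list(sim = sim, mat = mat, descriptors = desc_tab,
                 labels = labels, report = report, ordination = ord,
                 config_hash = hash))
}
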