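# Reproducible-run plumbing: validated run configurations, CSV writers
# matching the supplementary-data schemas, and a manifest sufficient to
# re-run each stage bit-identically. CSV is the sole tabular interchange
# format.

#' Build and validate a run configuration
#'
#' @param variants Variant id(s) to run.
#' @param glucose Initial glucose grid (mol/L).
#' @param horizon Simulation horizon (s).
#' @param grid_step Output grid spacing (s).
#' @param n Sensitivity batch size.
#' @param seed Integer seed for stochastic stages.
#' @param mixing_ratios Coculture Hpx-:wild-type ratios.
#' @param out_dir Output directory (created if absent).
#' @return A validated `run_config` list.
#' @export
run_config <- function(variants = "A", glucose = canonical_glucose_grid(),
                       horizon = 1e5, grid_step = 10, n = 2000L, seed = 1L,
                       mixing_ratios = 1, out_dir = tempfile("dampsim_")) {
  bad <- setdiff(variants, variant_ids())
  if (length(bad))
    stop("invalid variant(s) ", paste(bad, collapse = ", "),
         "; valid variants: ", paste(variant_ids(), collapse = ", "))
  if (!length(variants)) stop("at least one variant is required")
  if (any(glucose <= 0) || horizon <= 0 || grid_step <= 0 || n < 2 ||
      any(mixing_ratios <= 0))
    stop("invalid configuration value")
  structure(list(variants = variants, glucose = glucose, horizon = horizon,
                 grid_step = grid_step, n = as.integer(n),
                 seed = as.integer(seed), mixing_ratios = mixing_ratios,
                 out_dir = out_dir),
            class = "run_config")
}

.ensure_out <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir))
    stop("cannot create output directory ", config$out_dir)
  config$out_dir
}

.write_manifest <- function(config, stage, extra = list()) {
  manifest <- c(list(stage = stage,
                     package_version = as.character(utils::packageVersion("dampsim")),
                     parameter_provenance = "packaged baseline configuration",
                     config = config[setdiff(names(config), "out_dir")]),
                extra)
  path <- file.path(config$out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a trajectory CSV
#'
#' Columns: `time_s`, each state variable, then `density_cfu_ml` and
#' `mutation_rate`.
#'
#' @param traj A `damp_trajectory`.
#' @param path Output path.
#' @param params Parameter set for the density conversion.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, params = attr(traj, "params")) {
  if (is.null(params)) params <- baseline_parameters()
  df <- as.data.frame(traj)
  names(df)[1L] <- "time_s"
  tot <- df$wtCell + df$mCell
  df$density_cfu_ml <- tot * params[["molML"]] / params[["GCperGen"]]
  df$mutation_rate <- ifelse(tot > 0, df$mCell / tot, NA_real_)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a sweep CSV
#'
#' Mirrors the per-model sweep schema: `model`, `eGlc0_M`, `final_density`,
#' `mutation_rate`.
#'
#' @param sweep A `damp_sweep`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  df <- data.frame(model = attr(sweep, "variant_id"),
                   eGlc0_M = sweep$eGlc0,
                   final_density = sweep$final_density,
                   mutation_rate = sweep$mutation_rate)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the simulation stage of a configuration
#'
#' For each configured variant: one trajectory CSV per glucose condition,
#' one sweep CSV, and a manifest.
#'
#' @param config A `run_config`.
#' @return Character vector of the files written, invisibly.
#' @export
export_simulation <- function(config) {
  .ensure_out(config)
  files <- character(0)
  for (v in config$variants) {
    sw <- run_glucose_sweep(v, glucose_list = config$glucose,
                            horizon = config$horizon,
                            grid_step = config$grid_step,
                            keep_trajectories = TRUE)
    trajs <- attr(sw, "trajectories")
    for (i in seq_along(trajs)) {
      f <- file.path(config$out_dir,
                     sprintf("trajectory_%s_%02d.csv", v, i))
      write_trajectory_csv(trajs[[i]], f)
      files <- c(files, f)
    }
    f <- file.path(config$out_dir, sprintf("sweep_%s.csv", v))
    write_sweep_csv(sw, f)
    files <- c(files, f)
  }
  files <- c(files, .write_manifest(config, "simulate"))
  invisible(files)
}

#' Export the per-variant DAMP slope table
#'
#' @param config A `run_config`.
#' @return Path of the CSV written, invisibly; one row per variant with
#'   `variant`, `slope`, `ci95`, `r2`, `n`.
#' @export
export_slope_table <- function(config) {
  .ensure_out(config)
  tab <- slope_table(config$variants, horizon = config$horizon)
  f <- file.path(config$out_dir, "slopes.csv")
  write.csv(tab, f, row.names = FALSE)
  .write_manifest(config, "slopes")
  invisible(f)
}

#' Export a sensitivity-analysis run
#'
#' Writes one row per parameter set (factors, slope, R-squared, filter
#' verdicts) plus a summary CSV with the per-stage survivor counts.
#'
#' @param config A `run_config` (first variant used).
#' @return Character vector of files written, invisibly.
#' @export
export_sensitivity <- function(config) {
  .ensure_out(config)
  v <- config$variants[1L]
  batch <- sample_parameter_sets(config$n, seed = config$seed, variant = v)
  batch <- evaluate_batch(v, batch, glucose_list = config$glucose,
                          horizon = config$horizon)
  filt <- apply_filters(batch)
  sets <- cbind(as.data.frame(batch$factors), batch$outcomes, filt$pass)
  f1 <- file.path(config$out_dir, sprintf("sensitivity_sets_%s.csv", v))
  write.csv(sets, f1, row.names = FALSE)
  f2 <- file.path(config$out_dir, sprintf("sensitivity_summary_%s.csv", v))
  write.csv(data.frame(model = v, t(filt$counts)), f2, row.names = FALSE)
  .write_manifest(config, "sensitivity", list(variant = v))
  invisible(c(f1, f2))
}

#' Export a coculture sweep
#'
#' @param config A `run_config` (its `mixing_ratios` and glucose grid).
#' @return Character vector of files written, invisibly.
#' @export
export_coculture <- function(config) {
  .ensure_out(config)
  sw <- run_coculture_sweep(glucose_list = config$glucose,
                            mixing_ratios = config$mixing_ratios,
                            horizon = config$horizon)
  f1 <- file.path(config$out_dir, "coculture_sweep.csv")
  write.csv(sw, f1, row.names = FALSE)
  f2 <- file.path(config$out_dir, "coculture_slopes.csv")
  write.csv(coculture_slope_table(sw), f2, row.names = FALSE)
  .write_manifest(config, "coculture")
  invisible(c(f1, f2))
}

#' Export a synthetic fluctuation dataset
#'
#' Writes the raw-schema culture table, the per-assay generator truth, and
#' a plain-text column-description file.
#'
#' @param config A `run_config` (its `seed`).
#' @param n_assays,true_slope Passed to [generate_study_like_dataset()].
#' @return Character vector of files written, invisibly.
#' @export
export_fluctuation <- function(config, n_assays = 70L, true_slope = -0.83) {
  .ensure_out(config)
  ds <- generate_study_like_dataset(n_assays, true_slope, seed = config$seed)
  f1 <- file.path(config$out_dir, "fluctuation_cultures.csv")
  write.csv(ds$cultures, f1, row.names = FALSE)
  f2 <- file.path(config$out_dir, "fluctuation_assays_truth.csv")
  write.csv(ds$assays, f2, row.names = FALSE)
  f3 <- file.path(config$out_dir, "fluctuation_columns.txt")
  writeLines(c(
    "fluctuation_cultures.csv columns:",
    "  assay_id      integer assay identifier (one density level per assay)",
    "  treatment     treatment label",
    "  culture       parallel-culture index within the assay",
    "  N0            initial population size (cells)",
    "  Nt            final population size (cells, after any death thinning)",
    "  mutant_count  observed mutant colony count",
    "  mixing_ratio  Hpx-:wild-type ratio (NA outside cocultures)",
    "",
    "fluctuation_assays_truth.csv columns (generator truth, not observed):",
    "  assay_id, Nt, N0, m (true expected mutational events), w (fitness)"),
    f3)
  .write_manifest(config, "fluctuation",
                  list(n_assays = n_assays, true_slope = true_slope))
  invisible(c(f1, f2, f3))
}
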