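# Two-population extension of model D: a wild-type and an Hpx- population
# (no enzymatic peroxide degradation) sharing external glucose and an
# external peroxide pool.

#' Right-hand side of the wild-type/Hpx- coculture
#'
#' Convenience wrapper around [rhs()] for the `"D_coculture"` variant: both
#' populations draw on shared external glucose, the external peroxide pool
#' gains at the constant rate `ROSC2` and exchanges with each cytoplasm
#' scaled by that population's volume fraction, and only the wild-type
#' block carries the `O3` degradation sink.
#'
#' @param t Time (s, unused; the system is autonomous).
#' @param state Named 20-component coculture state
#'   (see `state_names("D_coculture")`).
#' @param params Baseline parameters.
#' @return Named derivative vector.
#' @export
rhs_coculture <- function(t = 0, state, params = baseline_parameters()) {
  rhs("D_coculture", t, state, params)
}

#' Coculture glucose sweep over mixing ratios
#'
#' Integrates the two-population model across the glucose grid for each
#' Hpx-:wild-type mixing ratio and reads out the focal (Hpx-) population's
#' final density and cumulative mutation rate, plus the total density.
#'
#' @param params Baseline parameters.
#' @param glucose_list Initial glucose conditions (mol/L).
#' @param mixing_ratios Hpx-:wild-type inoculum ratios (positive); the
#'   total Table-1 inoculum is split between the populations.
#' @param horizon Simulation horizon (s).
#' @return A data.frame with one row per (ratio, glucose) pair: `ratio`,
#'   `eGlc0`, `focal_density`, `focal_mutation_rate`, `total_density`;
#'   attribute `slopes` holds the per-ratio focal DAMP slope estimates.
#' @export
run_coculture_sweep <- function(params = baseline_parameters(),
                                glucose_list = canonical_glucose_grid(),
                                mixing_ratios = 1, horizon = 1e5) {
  if (any(!is.finite(mixing_ratios)) || any(mixing_ratios <= 0))
    stop("mixing_ratios must be positive")
  glucose_list <- sort(glucose_list)
  rows <- list()
  slopes <- list()
  for (ratio in mixing_ratios) {
    res <- lapply(glucose_list, function(g) {
      traj <- integrate_model("D_coculture", params, eGlc0 = g,
                              horizon = horizon, mixing_ratio = ratio)
      fin <- .traj_final(traj)
      hpx_tot <- fin[["wtCell_hpx"]] + fin[["mCell_hpx"]]
      data.frame(
        ratio = ratio, eGlc0 = g,
        focal_density = hpx_tot * params[["molML"]] / params[["GCperGen"]],
        focal_mutation_rate = fin[["mCell_hpx"]] / hpx_tot,
        total_density = (hpx_tot + fin[["wtCell"]] + fin[["mCell"]]) *
          params[["molML"]] / params[["GCperGen"]])
    })
    res <- do.call(rbind, res)
    rows[[as.character(ratio)]] <- res
    slopes[[as.character(ratio)]] <-
      loglog_slope(res$focal_density, res$focal_mutation_rate)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "slopes") <- slopes
  out
}

#' Focal Hpx- DAMP slopes across mixing ratios
#'
#' @param sweep Result of [run_coculture_sweep()].
#' @return Data.frame with one row per ratio: `ratio`, `slope`, `ci95`.
#' @export
coculture_slope_table <- function(sweep) {
  slopes <- attr(sweep, "slopes")
  if (is.null(slopes)) stop("sweep must come from run_coculture_sweep()")
  do.call(rbind, lapply(names(slopes), function(r)
    data.frame(ratio = as.numeric(r), slope = slopes[[r]]$slope,
               ci95 = slopes[[r]]$ci95)))
}
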