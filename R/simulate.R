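# Batch-culture integration and the glucose sweep.

#' Integrate a model variant over the batch-culture horizon
#'
#' Runs the compiled right-hand side through an adaptive stiff-capable
#' integrator (`deSolve::ode`, `lsoda`) with relative tolerance 1e-8 and
#' absolute tolerance 1e-14, sampling the solution on a uniform output
#' grid.
#'
#' @param variant A `variant_spec` or variant id.
#' @param params Baseline parameters.
#' @param eGlc0 Initial external glucose (mol/L).
#' @param horizon Simulation horizon (s), default 1e5 (27.8 h).
#' @param grid_step Output grid spacing (s), default 10.
#' @param mixing_ratio Coculture only: Hpx-:wild-type inoculum ratio.
#' @param times Optional explicit output times overriding the uniform grid
#'   (used internally by the sensitivity batches, which only need the
#'   final and penultimate-window states).
#' @param state0 Optional explicit initial state overriding
#'   [initial_state()].
#' @return A `damp_trajectory`: a data.frame with column `time` and one
#'   column per state variable, with attributes `variant_id`, `eGlc0` and
#'   `params`.
#' @examples
#' traj <- integrate_model("A", eGlc0 = 3.1e-4, horizon = 1e4)
#' tail(traj, 1)
#' @export
integrate_model <- function(variant, params = baseline_parameters(),
                            eGlc0, horizon = 1e5, grid_step = 10,
                            mixing_ratio = 1, times = NULL, state0 = NULL) {
  variant <- .as_variant(variant)
  if (is.null(times)) {
    if (!is.finite(horizon) || horizon <= 0) stop("horizon must be positive")
    if (!is.finite(grid_step) || grid_step <= 0)
      stop("grid_step must be positive")
    times <- seq(0, horizon, by = grid_step)
    if (times[length(times)] < horizon) times <- c(times, horizon)
  }
  if (is.null(state0))
    state0 <- initial_state(variant, eGlc0, mixing_ratio = mixing_ratio)
  else
    eGlc0 <- unname(state0[["eGlc"]])
  y0 <- .pad_state(variant, state0)
  pv <- unname(.pack_parms(variant, params))
  func <- if (variant$variant_id == "D_coculture") "dampsim_derivs_cocult"
          else "dampsim_derivs_mono"
  sol <- deSolve::ode(y = y0, times = times, func = func, parms = pv,
                      dllname = "dampsim", initfunc = "dampsim_initmod",
                      method = "lsoda", rtol = 1e-8, atol = 1e-14,
                      maxsteps = 5e5)
  diag <- attributes(sol)$istate
  if (!is.null(diag) && diag[1] < 0)
    stop("integration error for variant ", variant$variant_id,
         " at t = ", max(sol[, 1]), " s (istate = ", diag[1], ")")
  if (nrow(sol) < length(times) || any(!is.finite(sol)))
    stop("integration error for variant ", variant$variant_id,
         ": non-finite state near t = ", max(sol[, 1]), " s")
  out <- as.data.frame(sol)
  nm <- state_names(variant)
  if (variant$variant_id == "D_coculture") {
    names(out) <- c("time", nm)
  } else {
    names(out) <- c("time", .state_names_std, "ROSexternal")
    out <- out[, c("time", nm)]
  }
  # the clamp guards solver undershoot; report states on the admissible set
  out[, -1][out[, -1] < 0] <- 0
  structure(out, class = c("damp_trajectory", "data.frame"),
            variant_id = variant$variant_id, eGlc0 = eGlc0, params = params)
}

.traj_final <- function(traj) {
  s <- unlist(traj[nrow(traj), -1])
  s
}

#' Has a trajectory reached stationary phase?
#'
#' Stationarity is an average gain of fewer than 1 cell per 10 s output
#' step across the final 1,000 steps (2.7 h) of the simulation.
#'
#' @param traj A `damp_trajectory` covering at least 1,000 grid steps.
#' @param params Parameter set for the density conversion.
#' @param window Number of trailing grid steps examined (default 1000).
#' @return `TRUE` if stationary.
#' @export
is_stationary <- function(traj, params = attr(traj, "params"),
                          window = 1000L) {
  n <- nrow(traj)
  if (n < window + 1L)
    stop("trajectory must cover at least ", window, " grid steps")
  if (is.null(params)) params <- baseline_parameters()
  d_end <- density_cfu_per_ml(.traj_final(traj), params)
  d_prev <- density_cfu_per_ml(unlist(traj[n - window, -1]), params)
  (d_end - d_prev) / window < 1
}

#' Run a variant across a glucose sweep
#'
#' Integrates one trajectory per initial-glucose condition and extracts the
#' final density and final cumulative mutation rate.
#'
#' @param variant A `variant_spec` or variant id.
#' @param params Baseline parameters.
#' @param glucose_list Initial glucose concentrations (mol/L), default the
#'   canonical 5-point log grid.
#' @param horizon Simulation horizon (s).
#' @param grid_step Output grid spacing (s).
#' @param keep_trajectories Keep the full trajectories in the result?
#' @param allow_failures If `TRUE`, a condition on which the solver fails
#'   (possible for the pole-carrying MutT-regulation variants G and I) is
#'   recorded as an `NA` row instead of raising; the failure message is
#'   kept in the `failures` attribute.
#' @return A `damp_sweep`: data.frame with one row per condition (ordered by
#'   `eGlc0`) and columns `eGlc0`, `final_density`, `mutation_rate`,
#'   `stationary`; if requested, attribute `trajectories` holds the runs.
#' @examples
#' \donttest{
#' sw <- run_glucose_sweep("A")
#' sw
#' }
#' @export
run_glucose_sweep <- function(variant, params = baseline_parameters(),
                              glucose_list = canonical_glucose_grid(),
                              horizon = 1e5, grid_step = 10,
                              keep_trajectories = FALSE,
                              allow_failures = FALSE) {
  variant <- .as_variant(variant)
  if (!length(glucose_list) || any(glucose_list <= 0))
    stop("glucose_list must be non-empty and positive")
  glucose_list <- sort(glucose_list)
  trajs <- vector("list", length(glucose_list))
  failures <- character(0)
  rows <- lapply(seq_along(glucose_list), function(i) {
    g <- glucose_list[i]
    traj <- tryCatch(
      suppressWarnings(
        integrate_model(variant, params, eGlc0 = g, horizon = horizon,
                        grid_step = grid_step)),
      error = function(e) {
        msg <- paste0("condition eGlc0 = ", signif(g, 4), " M: ",
                      conditionMessage(e))
        if (!allow_failures) stop(msg, call. = FALSE)
        failures <<- c(failures, msg)
        NULL
      })
    if (is.null(traj))
      return(data.frame(eGlc0 = g, final_density = NA_real_,
                        mutation_rate = NA_real_, stationary = NA))
    if (keep_trajectories) trajs[[i]] <<- traj
    fin <- .traj_final(traj)
    data.frame(eGlc0 = g,
               final_density = density_cfu_per_ml(fin, params),
               mutation_rate = mutation_rate(fin),
               stationary = nrow(traj) > 1000L && is_stationary(traj, params))
  })
  out <- do.call(rbind, rows)
  attr(out, "variant_id") <- variant$variant_id
  if (keep_trajectories) attr(out, "trajectories") <- trajs
  if (length(failures)) attr(out, "failures") <- failures
  class(out) <- c("damp_sweep", "data.frame")
  out
}

#' DAMP slope table for a set of variants
#'
#' Runs the canonical glucose sweep for each requested variant and fits the
#' log-log slope of final mutation rate on final density. A condition on
#' which the solver fails (the near-pole MutT up-regulation variants G and
#' I can diverge at high glucose) is dropped from the fit, which then uses
#' the remaining conditions; at least 3 completed conditions are required.
#'
#' @param variants Character vector of variant ids (default A to K).
#' @param params Baseline parameters.
#' @param horizon Simulation horizon (s).
#' @return Data.frame with one row per variant: `variant`, `slope`, `ci95`
#'   (95% CI half-width), `r2`, `n` (conditions used in the fit).
#' @export
slope_table <- function(variants = setdiff(variant_ids(), "D_coculture"),
                        params = baseline_parameters(), horizon = 1e5) {
  if (!length(variants)) stop("no variants requested; valid variants: ",
                              paste(variant_ids(), collapse = ", "))
  rows <- lapply(variants, function(v) {
    sw <- run_glucose_sweep(v, params, horizon = horizon,
                            allow_failures = TRUE)
    ok <- is.finite(sw$final_density) & is.finite(sw$mutation_rate)
    if (sum(ok) < 3L)
      stop("variant ", v, ": fewer than 3 conditions completed")
    est <- loglog_slope(sw$final_density[ok], sw$mutation_rate[ok])
    data.frame(variant = v, slope = est$slope, ci95 = est$ci95,
               r2 = est$r2, n = est$n)
  })
  do.call(rbind, rows)
}
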