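# Global sensitivity analysis: log-spaced multiplicative perturbation of
# all model parameters with independent shuffling, five-stage filtering,
# slope summaries and Spearman rank associations.

# parameters perturbed for every variant: the kinetic constants and the
# fitted stoichiometry, but not the physical conversion constants
.perturbed_baseline <- c("U1", "M1", "Ks", "I1", "D1", "O2", "I2", "D2",
                         "C1", "C2", "R1", "S", "r", "O3", "R2", "Met1")

.perturbed_names <- function(variant) {
  variant <- .as_variant(variant)
  c(.perturbed_baseline, names(variant$extra_params))
}

#' Sample a batch of perturbed parameter sets
#'
#' Each perturbed parameter receives the same deterministic log-spaced grid
#' of multiplicative factors spanning `range[1]` to `range[2]` times its
#' baseline value (default 0.1x to 10x); the columns are then independently
#' permuted under the given seed so that no two parameters are correlated.
#'
#' @param n Number of parameter sets (>= 2).
#' @param params Baseline parameters.
#' @param seed Integer seed; the batch is fully reproducible from it.
#' @param variant Variant whose parameters (including its extra constants)
#'   are perturbed; default the baseline model `"A"`.
#' @param range Multiplicative perturbation range, default `c(0.1, 10)`.
#' @return A `sensitivity_batch` with the factor matrix (`n` sets by
#'   p parameters), the effective baseline values, variant, seed and range;
#'   outcomes are filled in by [evaluate_batch()].
#' @export
sample_parameter_sets <- function(n, params = baseline_parameters(), seed,
                                  variant = "A", range = c(0.1, 10)) {
  if (!is.numeric(n) || n < 2L) stop("n must be at least 2")
  if (missing(seed)) stop("a seed is required")
  variant <- .as_variant(variant)
  nms <- .perturbed_names(variant)
  grid <- if (range[1] == range[2]) rep(range[1], n)
          else 10^seq(log10(range[1]), log10(range[2]), length.out = n)
  factors <- matrix(NA_real_, nrow = n, ncol = length(nms),
                    dimnames = list(NULL, nms))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (j in seq_along(nms)) factors[, j] <- grid[sample.int(n)]
  structure(list(factors = factors,
                 baseline = variant_parameters(variant, params)[nms],
                 params = params, variant_id = variant$variant_id,
                 seed = seed, range = range, outcomes = NULL),
            class = "sensitivity_batch")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Evaluate a sensitivity batch
#'
#' Runs the glucose sweep for every perturbed parameter set and records the
#' per-condition final density, mutation rate and stationarity, plus the
#' fitted log-log slope and its R-squared. Solver failures are recorded as
#' not-complete rather than raised.
#'
#' @param variant Variant to simulate (must match the batch).
#' @param batch A `sensitivity_batch` from [sample_parameter_sets()].
#' @param glucose_list Initial glucose conditions (mol/L).
#' @param horizon Simulation horizon (s).
#' @return The batch with `outcomes` (data.frame: `complete`, `slope`,
#'   `r2`), `densities`, `rates` and `stationary` matrices filled.
#' @export
evaluate_batch <- function(variant, batch,
                           glucose_list = canonical_glucose_grid(),
                           horizon = 1e5) {
  variant <- .as_variant(variant)
  if (!inherits(batch, "sensitivity_batch"))
    stop("batch must come from sample_parameter_sets()")
  if (variant$variant_id != batch$variant_id)
    stop("batch was sampled for variant ", batch$variant_id)
  glucose_list <- sort(glucose_list)
  n <- nrow(batch$factors)
  k <- length(glucose_list)
  dens <- rates <- matrix(NA_real_, n, k)
  statn <- matrix(NA, n, k)
  complete <- logical(n)
  slope <- r2 <- rep(NA_real_, n)
  pv0 <- unname(.pack_parms(variant, batch$params))
  names(pv0) <- c(.param_names, "variant_code", .extra_names)
  nms <- colnames(batch$factors)
  # stationarity uses the density gain across the last 1,000 10-s steps,
  # so only three output times are needed per run
  times <- c(0, horizon - 1e4, horizon)
  for (i in seq_len(n)) {
    pv <- pv0
    pv[nms] <- batch$baseline * batch$factors[i, ]
    ok <- TRUE
    for (j in seq_len(k)) {
      res <- tryCatch(
        .integrate_endpoints(variant, unname(pv), glucose_list[j], times),
        error = function(e) NULL)
      if (is.null(res)) { ok <- FALSE; break }
      d_end <- density_cfu_per_ml(res$final, batch$params)
      d_pre <- density_cfu_per_ml(res$penultimate, batch$params)
      dens[i, j] <- d_end
      rates[i, j] <- if (res$final[["wtCell"]] + res$final[["mCell"]] > 0)
        mutation_rate(res$final) else NA_real_
      statn[i, j] <- (d_end - d_pre) / 1000 < 1
      if (!is.finite(dens[i, j]) || !is.finite(rates[i, j])) { ok <- FALSE; break }
    }
    complete[i] <- ok
    if (ok && all(dens[i, ] > 0) && all(rates[i, ] > 0)) {
      est <- loglog_slope(dens[i, ], rates[i, ])
      slope[i] <- est$slope
      r2[i] <- est$r2
    } else if (ok) {
      # a defined sweep whose rates include zeros has no log-log slope
      complete[i] <- FALSE
    }
  }
  batch$glucose_list <- glucose_list
  batch$outcomes <- data.frame(complete = complete, slope = slope, r2 = r2)
  batch$densities <- dens
  batch$rates <- rates
  batch$stationary <- statn
  batch
}

# low-level integration returning only the states at horizon and at
# horizon - 1e4 s; pv is the packed parameter vector
.integrate_endpoints <- function(variant, pv, eGlc0, times) {
  state0 <- initial_state(variant, eGlc0)
  y0 <- .pad_state(variant, state0)
  func <- if (variant$variant_id == "D_coculture") "dampsim_derivs_cocult"
          else "dampsim_derivs_mono"
  sol <- suppressWarnings(
    deSolve::ode(y = y0, times = times, func = func, parms = pv,
                 dllname = "dampsim", initfunc = "dampsim_initmod",
                 method = "lsoda", rtol = 1e-8, atol = 1e-14,
                 maxsteps = 5e5))
  diag <- attributes(sol)$istate
  if ((!is.null(diag) && diag[1] < 0) || nrow(sol) < length(times) ||
      any(!is.finite(sol)))
    stop("integration error")
  full_nm <- if (variant$variant_id == "D_coculture") state_names(variant)
             else c(.state_names_std, "ROSexternal")
  fin <- pmax(setNames(sol[nrow(sol), -1], full_nm), 0)
  pen <- pmax(setNames(sol[nrow(sol) - 1L, -1], full_nm), 0)
  list(final = fin, penultimate = pen)
}

#' Apply the five acceptance filters to an evaluated batch
#'
#' Filters, applied cumulatively: (1) stationary phase reached in every
#' glucose condition; (2) every final density within (1e7, 1e10) cells/ml;
#' (3) final density strictly increasing with glucose; (4) every mutation
#' rate within (2e-12, 2e-8); (5) log-log fit R-squared above 0.5.
#'
#' @param batch An evaluated `sensitivity_batch` (or a compatible list with
#'   `outcomes`, `densities`, `rates`, `stationary`).
#' @return A `filter_report`: list with `counts` (named vector `complete`,
#'   `f1`..`f5`, non-increasing) and `pass` (logical data.frame of per-set
#'   verdicts, monotone across stages).
#' @export
apply_filters <- function(batch) {
  oc <- batch$outcomes
  if (is.null(oc)) stop("batch has no outcomes; run evaluate_batch() first")
  complete <- oc$complete
  all_true <- function(m) apply(m, 1L, function(x) all(!is.na(x)) && all(x))
  f1 <- complete & all_true(batch$stationary)
  f2 <- f1 & all_true(batch$densities > 1e7 & batch$densities < 1e10)
  f3 <- f2 & apply(batch$densities, 1L, function(x)
    all(!is.na(x)) && all(diff(x) > 0))
  f4 <- f3 & all_true(batch$rates > 2e-12 & batch$rates < 2e-8)
  f5 <- f4 & !is.na(oc$r2) & oc$r2 > 0.5
  pass <- data.frame(complete = complete, f1 = f1, f2 = f2, f3 = f3,
                     f4 = f4, f5 = f5)
  structure(list(counts = vapply(pass, sum, integer(1)), pass = pass),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Sensitivity filter report (surviving sets per stage):\n")
  print(x$counts)
  invisible(x)
}

#' Summarise surviving DAMP slopes
#'
#' Median and interquartile range (quartiles by linear interpolation) of
#' the slopes surviving all five filters.
#'
#' @param batch An evaluated `sensitivity_batch`, or a plain numeric vector
#'   of slopes.
#' @param filters A `filter_report`; computed from the batch if omitted.
#' @return List with `median`, `q1`, `q3`, `n`.
#' @export
summarize_slopes <- function(batch, filters = NULL) {
  slopes <- if (is.numeric(batch)) {
    batch
  } else {
    if (is.null(filters)) filters <- apply_filters(batch)
    batch$outcomes$slope[filters$pass$f5]
  }
  if (length(slopes) < 4L)
    stop("at least 4 surviving slopes are required")
  q <- quantile(slopes, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2L], q1 = q[1L], q3 = q[3L], n = length(slopes))
}

#' Spearman rank associations of parameters with slope and mutation rate
#'
#' For each perturbed parameter, the Spearman rank correlation of its
#' multiplicative factor against the DAMP slope and against the mutation
#' rate at the condition nearest 250 mg/L glucose (the middle of the
#' canonical grid), across the sets surviving all filters. Ties take
#' average ranks; a constant parameter column yields `NA` rather than an
#' error.
#'
#' @param batch An evaluated `sensitivity_batch`.
#' @param filters A `filter_report`; computed from the batch if omitted.
#' @return Data.frame with one row per parameter: `parameter`, `rho_slope`,
#'   `p_slope`, `rho_rate`, `p_rate`, ordered by decreasing `|rho_slope|`.
#' @export
rank_correlations <- function(batch, filters = NULL) {
  if (is.null(filters)) filters <- apply_filters(batch)
  keep <- filters$pass$f5
  if (sum(keep) < 10L) stop("at least 10 surviving sets are required")
  slopes <- batch$outcomes$slope[keep]
  mid <- which.min(abs(log(batch$glucose_list) -
                       log(glucose_mgL_to_molar(250))))
  rate_mid <- batch$rates[keep, mid]
  one <- function(x, y) {
    if (length(unique(x)) < 2L || length(unique(y)) < 2L)
      return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  }
  nms <- colnames(batch$factors)
  out <- do.call(rbind, lapply(nms, function(p) {
    f <- batch$factors[keep, p]
    s <- one(f, slopes)
    m <- one(f, rate_mid)
    data.frame(parameter = p, rho_slope = s[1L], p_slope = s[2L],
               rho_rate = m[1L], p_rate = m[2L])
  }))
  out[order(-abs(out$rho_slope)), , drop = FALSE]
}
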