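# Synthetic fluctuation assays: Luria-Delbruck mutant-count machinery with
# a mutant relative-fitness parameter, simulation of parallel cultures in
# the study's raw-data schema, and maximum-likelihood / p0 estimators of
# the expected number of mutational events m.

#' Mutant clone-size distribution
#'
#' Probability that a single mutation, arising uniformly over the
#' deterministic growth of the culture, leaves a clone of `j` cells at
#' plating, for a mutant with relative fitness `w`:
#' `q_j = rho * Gamma(j) * Gamma(rho + 1) / Gamma(j + rho + 1)` with
#' `rho = 1/w` (the Lea-Coulson law generalised to differential fitness).
#' At `w = 1` this reduces to `q_j = 1 / (j * (j + 1))`.
#'
#' @param w Mutant relative fitness (> 0).
#' @param jmax Largest clone size returned.
#' @param renormalise Rescale so the returned probabilities sum to 1
#'   (default); the raw truncated law is used internally by [ld_pmf()].
#' @return Numeric vector `q[1..jmax]`.
#' @examples
#' clone_size_distribution(1, 3, renormalise = FALSE)  # 1/2, 1/6, 1/12
#' @export
clone_size_distribution <- function(w, jmax, renormalise = TRUE) {
  if (!is.finite(w) || w <= 0) stop("w must be positive")
  if (jmax < 1L) stop("jmax must be at least 1")
  rho <- 1 / w
  j <- seq_len(jmax)
  q <- exp(log(rho) + lgamma(j) + lgamma(rho + 1) - lgamma(j + rho + 1))
  if (renormalise) q / sum(q) else q
}

#' Luria-Delbruck mutant-count distribution
#'
#' Probability of observing `0..nmax` mutant cells in a culture with `m`
#' expected mutational events and mutant relative fitness `w`, by the
#' standard convolution recursion: `p_0 = exp(-m)`,
#' `p_n = (m / n) * sum_{j=1..n} j * q_j * p_{n-j}`.
#'
#' @param m Expected mutational events per culture (>= 0).
#' @param w Mutant relative fitness.
#' @param nmax Largest count returned.
#' @return Numeric vector `p[0..nmax]` (length `nmax + 1`); the deficit
#'   from 1 is the tail mass beyond `nmax`.
#' @examples
#' ld_pmf(1, 1, 2)  # exp(-1), exp(-1)/2, ...
#' @export
ld_pmf <- function(m, w = 1, nmax) {
  if (!is.finite(m) || m < 0) stop("m must be non-negative")
  if (nmax < 0L) stop("nmax must be non-negative")
  p <- numeric(nmax + 1L)
  p[1L] <- exp(-m)
  if (nmax >= 1L) {
    q <- clone_size_distribution(w, nmax, renormalise = FALSE)
    jq <- seq_len(nmax) * q
    for (n in seq_len(nmax))
      p[n + 1L] <- (m / n) * sum(jq[seq_len(n)] * p[n:1L])
  }
  p
}

#' Simulate one fluctuation assay
#'
#' Parallel cultures grow deterministically from `N0` to `Nt` cells; each
#' culture acquires `Poisson(m)` mutations with `m = mu_per_division *
#' (Nt - N0)`, each mutation founds a clone of `floor(u^-w)` cells
#' (`u` uniform), capped at `Nt`. Plating retains each mutant cell with
#' probability `plating_fraction`; death removes a `death_fraction` of all
#' cells before plating (thinning both the mutant count and the reported
#' `Nt`).
#'
#' @param n_cultures Number of parallel cultures.
#' @param N0,Nt Initial and final population sizes (cells), `Nt > N0 >= 1`.
#' @param mu_per_division Mutation probability per cell division.
#' @param w Mutant relative fitness.
#' @param plating_fraction Fraction of the culture plated, in `[0, 1]`.
#' @param death_fraction Fraction of cells lost before plating, in `[0, 1)`.
#' @param seed Integer seed (required; no implicit nondeterminism).
#' @param assay_id,treatment Labels copied into the output.
#' @return Data.frame in the raw-assay schema: `assay_id`, `treatment`,
#'   `N0`, `Nt`, `mutant_count`, `mixing_ratio`; the generator truth (`m`,
#'   `w`, `plating_fraction`, `death_fraction`) is carried in the
#'   `"truth"` attribute, separate from the observed columns.
#' @export
simulate_assay <- function(n_cultures, N0, Nt, mu_per_division, w = 1,
                           plating_fraction = 1, death_fraction = 0, seed,
                           assay_id = 1L, treatment = "synthetic") {
  if (missing(seed)) stop("a seed is required")
  if (Nt <= N0 || N0 < 1) stop("need Nt > N0 >= 1")
  if (mu_per_division < 0 || plating_fraction < 0 || plating_fraction > 1 ||
      death_fraction < 0 || death_fraction >= 1)
    stop("parameters out of range")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  m <- mu_per_division * (Nt - N0)
  n_mut <- rpois(n_cultures, m)
  counts <- vapply(n_mut, function(k) {
    if (k == 0L) return(0)
    sizes <- pmin(floor(runif(k)^(-w)), Nt)
    sum(sizes)
  }, numeric(1))
  keep <- plating_fraction * (1 - death_fraction)
  observed <- if (keep < 1)
    vapply(counts, function(x) rbinom(1L, as.integer(min(x, .Machine$integer.max)),
                                      keep), integer(1))
  else as.integer(counts)
  out <- data.frame(assay_id = assay_id, treatment = treatment,
                    culture = seq_len(n_cultures),
                    N0 = N0, Nt = round(Nt * (1 - death_fraction)),
                    mutant_count = observed, mixing_ratio = NA_real_)
  attr(out, "truth") <- data.frame(assay_id = assay_id, m = m, w = w,
                                   plating_fraction = plating_fraction,
                                   death_fraction = death_fraction)
  out
}

# counts above this are winsorised before likelihood evaluation; jackpot
# cultures carry little information about m beyond "large"
.ml_count_cap <- 256L

.ld_loglik <- function(counts, m, w) {
  nmax <- max(counts)
  p <- ld_pmf(m, w, nmax)
  p <- pmax(p, 1e-300)
  sum(log(p[counts + 1L]))
}

#' Maximum-likelihood estimate of mutational events per culture
#'
#' Maximises the Luria-Delbruck likelihood of the observed mutant counts
#' over `m`, either with the mutant relative fitness `w` fixed, or
#' profiling `w` jointly (`w_mode = "free"`). Counts are winsorised at 256
#' before evaluation. The standard error comes from the observed
#' information at the optimum. If the free fit fails to converge it falls
#' back to the fixed-fitness fit at `w_fallback` (default 0.59, the
#' study-wide median mutant fitness) with a warning flag.
#'
#' @param counts Integer mutant counts, one per parallel culture (>= 2).
#' @param w_mode Either the string `"free"` or a fixed numeric fitness.
#' @param Nt Final population size; if supplied the mutation rate
#'   `mu = m / Nt` is reported.
#' @param w_fallback Fitness used when the free fit does not converge.
#' @return A `mutation_rate_estimate`: list with `m`, `se`, `w`,
#'   `w_estimated`, `mu`, `method = "ml"`, `converged`.
#' @export
estimate_m_ml <- function(counts, w_mode = "free", Nt = NULL,
                          w_fallback = 0.59) {
  if (length(counts) < 2L) stop("at least 2 cultures are required")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  counts <- as.integer(pmin(counts, .ml_count_cap))
  if (all(counts == 0L)) {
    return(structure(list(m = 0, se = NA_real_, w = NA_real_,
                          w_estimated = FALSE,
                          mu = if (is.null(Nt)) NA_real_ else 0,
                          method = "ml", converged = TRUE),
                     class = "mutation_rate_estimate"))
  }
  m0 <- max(-log(mean(counts == 0L) + 1e-10), 0.1)
  free <- identical(w_mode, "free")
  fell_back <- FALSE
  if (free) {
    fit <- tryCatch(
      optim(c(log(m0), 0),
            function(th) -.ld_loglik(counts, exp(th[1L]), exp(th[2L])),
            method = "Nelder-Mead", hessian = TRUE,
            control = list(maxit = 500)),
      error = function(e) NULL)
    ok <- !is.null(fit) && fit$convergence == 0 &&
      all(is.finite(fit$par)) && abs(fit$par[2L]) < 5
    if (ok) {
      vc <- tryCatch(solve(fit$hessian), error = function(e) NULL)
      se <- if (!is.null(vc) && vc[1L, 1L] > 0)
        exp(fit$par[1L]) * sqrt(vc[1L, 1L]) else NA_real_
      m_hat <- exp(fit$par[1L])
      return(structure(list(m = m_hat, se = se, w = exp(fit$par[2L]),
                            w_estimated = TRUE,
                            mu = if (is.null(Nt)) NA_real_ else m_hat / Nt,
                            method = "ml", converged = TRUE),
                       class = "mutation_rate_estimate"))
    }
    warning("free-fitness fit did not converge; falling back to fixed w = ",
            w_fallback)
    w_mode <- w_fallback
    fell_back <- TRUE
  }
  w <- as.numeric(w_mode)
  if (!is.finite(w) || w <= 0) stop("fixed w must be positive")
  fit <- optim(log(m0), function(th) -.ld_loglik(counts, exp(th), w),
               method = "Brent", lower = log(1e-6), upper = log(1e3),
               hessian = TRUE)
  se <- if (is.finite(fit$hessian[1L, 1L]) && fit$hessian[1L, 1L] > 0)
    exp(fit$par) / sqrt(fit$hessian[1L, 1L]) else NA_real_
  m_hat <- exp(fit$par)
  structure(list(m = m_hat, se = se, w = w, w_estimated = FALSE,
                 mu = if (is.null(Nt)) NA_real_ else m_hat / Nt,
                 method = "ml", converged = !fell_back),
            class = "mutation_rate_estimate")
}

#' p0 estimate of mutational events per culture
#'
#' `m = -ln(fraction of zero-mutant cultures)`. Applicable only when the
#' assay contains cultures both with and without mutants.
#'
#' @param counts Integer mutant counts.
#' @return A `mutation_rate_estimate` with `method = "p0"`; `se` is the
#'   delta-method standard error from the binomial variance of the zero
#'   fraction.
#' @export
estimate_m_p0 <- function(counts) {
  if (length(counts) < 2L) stop("at least 2 cultures are required")
  n0 <- sum(counts == 0)
  n <- length(counts)
  if (n0 == 0L || n0 == n)
    stop("p0 method inapplicable: need cultures both with and without mutants")
  p0 <- n0 / n
  structure(list(m = -log(p0), se = sqrt((1 - p0) / (n0)),
                 w = NA_real_, w_estimated = FALSE, mu = NA_real_,
                 method = "p0", converged = TRUE),
            class = "mutation_rate_estimate")
}

#' @export
print.mutation_rate_estimate <- function(x, ...) {
  cat(sprintf("m = %.4g (SE %.3g), method %s", x$m, x$se, x$method))
  if (x$w_estimated) cat(sprintf(", w-hat = %.3g", x$w))
  cat("\n")
  invisible(x)
}

#' Generate a study-like fluctuation dataset
#'
#' Builds a synthetic multi-assay dataset emulating the structure of the
#' study's raw fluctuation-assay table: per parallel culture a treatment
#' label, initial and final population size and mutant count. Final
#' densities span `density_range` (log-spaced across assays) and the
#' per-assay expected events are set so that log(m per ml) against
#' log(Nt per ml) has slope `true_slope + 1` — i.e. `true_slope` under the
#' events-minus-1 convention of [damp_slope_from_events()]. Initial
#' populations are drawn log-normally with median 3,000 cells.
#'
#' @param n_assays Number of assays (each a density level).
#' @param true_slope Designed DAMP slope (events-minus-1 convention).
#' @param seed Integer seed.
#' @param density_range Range of final populations (cells per 1-ml culture).
#' @param n_cultures Parallel cultures per assay.
#' @param m_at_mid Expected mutational events per culture at the geometric
#'   midpoint of `density_range`.
#' @param w Mutant relative fitness used by the generator.
#' @param treatment Treatment label.
#' @return A `fluctuation_dataset`: list with `cultures` (the raw-schema
#'   data.frame over all assays) and `assays` (per-assay truth: `assay_id`,
#'   `Nt`, true `m`, `w`).
#' @export
generate_study_like_dataset <- function(n_assays, true_slope, seed,
                                        density_range = c(1e7, 1e9),
                                        n_cultures = 16L, m_at_mid = 1,
                                        w = 1, treatment = "synthetic") {
  if (n_assays < 2L) stop("at least 2 assays (density levels) are required")
  if (missing(seed)) stop("a seed is required")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  Nt <- 10^seq(log10(density_range[1L]), log10(density_range[2L]),
               length.out = n_assays)
  mid <- sqrt(prod(density_range))
  m_true <- m_at_mid * (Nt / mid)^(true_slope + 1)
  # sdlog chosen so the lognormal N0 has median 3,000 and mean ~3,500 cells
  N0 <- pmax(round(rlnorm(n_assays, log(3000), 0.55)), 100)
  assay_seeds <- sample.int(.Machine$integer.max, n_assays)
  cultures <- do.call(rbind, lapply(seq_len(n_assays), function(i) {
    mu <- m_true[i] / (Nt[i] - N0[i])
    simulate_assay(n_cultures, N0[i], Nt[i], mu, w = w,
                   seed = assay_seeds[i], assay_id = i, treatment = treatment)
  }))
  rownames(cultures) <- NULL
  structure(list(cultures = cultures,
                 assays = data.frame(assay_id = seq_len(n_assays), Nt = Nt,
                                     N0 = N0, m = m_true, w = w)),
            class = "fluctuation_dataset")
}

#' Estimate per-assay mutational events across a fluctuation dataset
#'
#' @param dataset A `fluctuation_dataset` (or a data.frame in the raw
#'   schema with `assay_id`, `Nt`, `mutant_count` columns).
#' @param w_mode Passed to [estimate_m_ml()]; default fixed fitness 1.
#' @return Data.frame with one row per assay: `assay_id`, `Nt`, `m_hat`,
#'   `se`.
#' @export
estimate_dataset_m <- function(dataset, w_mode = 1) {
  cultures <- if (inherits(dataset, "fluctuation_dataset")) dataset$cultures
              else dataset
  do.call(rbind, lapply(split(cultures, cultures$assay_id), function(a) {
    est <- estimate_m_ml(a$mutant_count, w_mode = w_mode, Nt = a$Nt[1L])
    data.frame(assay_id = a$assay_id[1L], Nt = a$Nt[1L],
               m_hat = est$m, se = est$se)
  }))
}
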