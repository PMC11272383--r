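# Shared helpers: independent integrators and state generators used as
# oracles against the package's compiled solver path.

.spec <- function(variant) dampsim:::.as_variant(variant)

pv_for <- function(variant, params = baseline_parameters())
  unname(dampsim:::.pack_parms(.spec(variant), params))

pad_for <- function(variant, state) dampsim:::.pad_state(.spec(variant), state)

# integrate with deSolve but through the pure-R right-hand side (checks the
# compiled derivatives against their R reference along whole trajectories)
integrate_with_r_rhs <- function(variant, eGlc0, times,
                                 params = baseline_parameters(),
                                 method = "lsoda") {
  sp <- .spec(variant)
  pv <- pv_for(variant, params)
  core <- if (sp$variant_id == "D_coculture") dampsim:::.rhs_cocult_core
          else dampsim:::.rhs_mono_core
  y0 <- pad_for(variant, initial_state(variant, eGlc0))
  deSolve::ode(y0, times, function(t, y, p) list(core(y, pv)), NULL,
               method = method, rtol = 1e-8, atol = 1e-14, maxsteps = 5e5)
}

# fixed-step classical Runge-Kutta on the R right-hand side; fully
# independent of deSolve and of the compiled code
rk4_integrate <- function(variant, eGlc0, h, t_end,
                          params = baseline_parameters()) {
  sp <- .spec(variant)
  pv <- pv_for(variant, params)
  core <- if (sp$variant_id == "D_coculture") dampsim:::.rhs_cocult_core
          else dampsim:::.rhs_mono_core
  y <- pad_for(variant, initial_state(variant, eGlc0))
  n <- round(t_end / h)
  for (i in seq_len(n)) {
    k1 <- core(y, pv)
    k2 <- core(y + h / 2 * k1, pv)
    k3 <- core(y + h / 2 * k2, pv)
    k4 <- core(y + h * k3, pv)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# random admissible state within the model's operating ranges
random_state <- function(variant) {
  nm <- state_names(.spec(variant))
  s <- setNames(numeric(length(nm)), nm)
  s["eGlc"] <- runif(1, 1e-6, 6.2e-3)
  for (v in intersect(c("iGlc", "dGTP"), nm)) s[v] <- runif(1, 0, 2.3e-3)
  for (v in intersect(c("DNA", "wtCell", "mDNA", "mCell"), nm))
    s[v] <- runif(1, 0, 1e-8)
  for (v in intersect(c("ROS", "odGTP", "ROSexternal"), nm))
    s[v] <- runif(1, 0, 1.9e-7)
  s["cytVol"] <- runif(1, 1e-9, 1e-2)
  for (v in grep("_hpx$", nm, value = TRUE)) {
    base <- sub("_hpx$", "", v)
    s[v] <- s[base]
  }
  # keep the MutT up-regulation factors of G/H/I below their poles
  if (.spec(variant)$variant_id == "H") s["odGTP"] <- runif(1, 0, 7e-10)
  s
}

# reference slope values and 95% CI half-widths reported for the baseline
# glucose sweeps of the eleven model structures
reported_slopes <- data.frame(
  variant = c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K"),
  slope = c(0.09, -0.01, -0.001, -0.91, 0.09, -0.89, -0.28, 0.08, -0.62,
            0.10, 0.096),
  ci95 = c(0.016, 0.016, 0.03, 0.016, 0.016, 0.016, 0.016, 0.03, 0.016,
           0.016, 0.016))
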