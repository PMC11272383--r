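# Core model definitions: state layouts, initial conditions, the R
# reference implementation of every variant's right-hand side, and the
# density / mutation-rate readouts.

.state_names_std <- c("eGlc", "iGlc", "dGTP", "DNA", "wtCell", "ROS",
                      "odGTP", "mDNA", "mCell", "cytVol")
.hpx_block <- paste0(c("iGlc", "dGTP", "DNA", "wtCell", "ROS", "odGTP",
                       "mDNA", "mCell", "cytVol"), "_hpx")

#' State variable names for a model variant
#'
#' @param variant A `variant_spec` or variant id.
#' @return Character vector of state names in canonical order. Variant C has
#'   no `ROS` state (cytoplasmic peroxide is held constant); variants D and K
#'   add the extracellular pool `ROSexternal`; the coculture adds the nine
#'   `_hpx` mirrors of the cytoplasmic block.
#' @export
state_names <- function(variant) {
  variant <- .as_variant(variant)
  if (variant$variant_id == "D_coculture")
    return(c(.state_names_std, "ROSexternal", .hpx_block))
  nm <- .state_names_std
  if (variant$variant_id == "C") nm <- setdiff(nm, "ROS")
  c(nm, variant$extra_state)
}

# molar mass of D-glucose, g/mol
.glucose_molar_mass <- 180.156

#' Convert a glucose concentration from mg/L to molar
#'
#' @param mgL Glucose concentration in mg per litre (non-negative).
#' @return Concentration in mol/L.
#' @examples
#' glucose_mgL_to_molar(250)
#' @export
glucose_mgL_to_molar <- function(mgL) {
  if (any(!is.finite(mgL)) || any(mgL < 0))
    stop("glucose concentration must be non-negative")
  mgL / 1000 / .glucose_molar_mass
}

#' Canonical initial-glucose grid
#'
#' Five log-spaced initial external glucose concentrations from 3.1e-4 to
#' 6.2e-3 M, the molar equivalents of 55 to 1,100 mg/L.
#'
#' @return Numeric vector of length 5 (mol/L).
#' @export
canonical_glucose_grid <- function() {
  10^seq(log10(3.1e-4), log10(6.2e-3), length.out = 5L)
}

#' Initial state of a batch culture
#'
#' The inoculum fixes `wtCell = 8.5e-12` M of template-strand GC base pairs
#' and `cytVol = 2.25e-9` ml of total cytoplasm (about 2,175 cells in the
#' 1 ml culture); every other non-glucose variable starts at zero.
#'
#' @param variant A `variant_spec` or variant id.
#' @param eGlc0 Initial external glucose (mol/L), in (0, 0.1].
#' @param mixing_ratio For the coculture only: Hpx-:wild-type inoculum
#'   ratio; the Table-1 inoculum is split between the two populations.
#' @return Named numeric state vector in [state_names()] order.
#' @examples
#' initial_state("A", 3.1e-4)
#' @export
initial_state <- function(variant, eGlc0, mixing_ratio = 1) {
  variant <- .as_variant(variant)
  if (length(eGlc0) != 1L || !is.finite(eGlc0) || eGlc0 <= 0 || eGlc0 > 1e-1)
    stop("eGlc0 must lie in (0, 0.1] M")
  nm <- state_names(variant)
  s <- setNames(numeric(length(nm)), nm)
  s["eGlc"] <- eGlc0
  if (variant$variant_id == "D_coculture") {
    if (!is.finite(mixing_ratio) || mixing_ratio <= 0)
      stop("mixing_ratio must be positive")
    wt_frac <- 1 / (1 + mixing_ratio)
    s["wtCell"] <- 8.5e-12 * wt_frac
    s["cytVol"] <- 2.25e-9 * wt_frac
    s["wtCell_hpx"] <- 8.5e-12 * (1 - wt_frac)
    s["cytVol_hpx"] <- 2.25e-9 * (1 - wt_frac)
  } else {
    s["wtCell"] <- 8.5e-12
    s["cytVol"] <- 2.25e-9
  }
  s
}

# --- R reference right-hand sides -------------------------------------------
# Positional layout shared with src/damp_models.c:
# parms: 1..19 baseline constants in .param_names order, 20 variant code,
#        21..35 extras in .extra_names order.
# mono state (padded): eGlc iGlc dGTP DNA wtCell ROS odGTP mDNA mCell cytVol
#                      ROSexternal  (ROS slot inert for variant C)
# coculture state: eGlc, wild-type block (9), ROSexternal, Hpx- block (9).

.rhs_mono_core <- function(y, pv) {
  y <- pmax(y, 0)
  U1 <- pv[1L]; M1 <- pv[2L]; Ks <- pv[3L]; I1 <- pv[4L]; D1 <- pv[5L]
  O2 <- pv[6L]; I2 <- pv[7L]; D2 <- pv[8L]; C1 <- pv[9L]; C2 <- pv[10L]
  R1 <- pv[11L]; S <- pv[12L]; r <- pv[13L]; O3 <- pv[14L]; R2 <- pv[15L]
  Met1 <- pv[16L]; CellVol <- pv[17L]; molML <- pv[18L]; GCperGen <- pv[19L]
  code <- pv[20L]
  eGlc <- y[1L]; iGlc <- y[2L]; dGTP <- y[3L]; DNA <- y[4L]; wt <- y[5L]
  ROS <- y[6L]; od <- y[7L]; mDNA <- y[8L]; cytVol <- y[10L]; ROSext <- y[11L]

  # uptake flux in the culture frame; gated off once glucose is exhausted.
  # The upregulated-importer law of variant B keeps a positive flux at
  # eGlc = 0, unlike Monod kinetics, so it carries a smooth exhaustion
  # factor on the nanomolar scale (far below Ks).
  if (eGlc <= 0) {
    uptake <- 0
  } else if (code == 2) {
    U2 <- pv[21L]; K2 <- pv[22L]
    uptake <- U1 * wt * (U2 - eGlc) / (U2 - eGlc + K2) * eGlc / (eGlc + 1e-9)
  } else {
    uptake <- U1 * wt * eGlc / (eGlc + Ks)
  }

  ROSeff <- if (code == 3) pv[23L] else ROS   # variant C: constant peroxide
  oxid <- dGTP * ROSeff * O2

  d <- numeric(11L)
  d[1L] <- -uptake
  d[2L] <- uptake / cytVol - Met1 * M1 * iGlc
  d[3L] <- M1 * iGlc - I1 * dGTP - oxid
  d[4L] <- I1 * dGTP + C2 * mDNA + S * mDNA + R1 * od - D1 * DNA
  d[5L] <- (D1 * DNA + R2 * mDNA) * cytVol
  # cytoplasmic peroxide balance
  if (code == 3) {
    d[6L] <- 0
  } else if (code == 4) {                       # D: external source + diffusion
    kdiff <- pv[25L]
    d[6L] <- kdiff * (ROSext - ROS) - oxid - O3 * ROS
  } else if (code == 5) {                       # E: glucose-gated degradation
    C3 <- pv[26L]
    d[6L] <- M1 * r * iGlc - oxid - O3 * ROS * iGlc / (iGlc + C3)
  } else if (code == 6) {                       # F: density-dependent degradation
    C3a <- pv[27L]
    d[6L] <- M1 * r * iGlc - oxid - ROS * (molML / GCperGen) * wt * C3a
  } else if (code == 11) {                      # K: Ahp + Kat Michaelis-Menten
    kAhp <- pv[32L]; kmAhp <- pv[33L]; kKat <- pv[34L]; kmKat <- pv[35L]
    kdiff <- pv[25L]
    d[6L] <- M1 * r * iGlc - oxid - kAhp * ROS / (ROS + kmAhp) -
      kKat * ROS / (ROS + kmKat) - kdiff * (ROS - ROSext)
  } else {
    d[6L] <- M1 * r * iGlc - oxid - O3 * ROS
  }
  # oxidised nucleotide pool; variants G-J modify the MutT term (and, as
  # printed, drop the R1 incorporation sink). G/H/I up-regulate MutT by
  # the factor 1/(1 - X/C3x), whose pole sits just above the operating
  # range of the regulator X.
  if (code == 7) {
    C3G <- pv[28L]
    d[7L] <- oxid - C1 * od / (1 - iGlc / C3G) - I2 * od
  } else if (code == 8) {
    C3b <- pv[29L]
    d[7L] <- oxid - C1 * od / (1 - od / C3b) - I2 * od
  } else if (code == 9) {
    C3c <- pv[30L]
    d[7L] <- oxid - C1 * od / (1 - ROS / C3c) - I2 * od
  } else if (code == 10) {
    Kt <- pv[31L]
    d[7L] <- oxid - C1 * od * od / (od + Kt) - I2 * od
  } else {
    d[7L] <- oxid - C1 * od - I2 * od - R1 * od
  }
  d[8L] <- I2 * od - D2 * mDNA - C2 * mDNA - S * mDNA - R2 * mDNA
  d[9L] <- D2 * mDNA * cytVol
  d[10L] <- (D1 * DNA + R2 * mDNA) * cytVol * molML / GCperGen * CellVol
  # external peroxide pool (variants D and K only)
  if (code == 4) {
    ROSC2 <- pv[24L]; kdiff <- pv[25L]
    d[11L] <- ROSC2 + cytVol / (1 - cytVol) * kdiff * (ROS - ROSext)
  } else if (code == 11) {
    kdiff <- pv[25L]
    d[11L] <- kdiff * (ROS - ROSext) * cytVol / (1 - cytVol)
  } else {
    d[11L] <- 0
  }
  d
}

.rhs_cocult_core <- function(y, pv) {
  y <- pmax(y, 0)
  U1 <- pv[1L]; M1 <- pv[2L]; Ks <- pv[3L]; I1 <- pv[4L]; D1 <- pv[5L]
  O2 <- pv[6L]; I2 <- pv[7L]; D2 <- pv[8L]; C1 <- pv[9L]; C2 <- pv[10L]
  R1 <- pv[11L]; S <- pv[12L]; O3 <- pv[14L]; R2 <- pv[15L]
  Met1 <- pv[16L]; CellVol <- pv[17L]; molML <- pv[18L]; GCperGen <- pv[19L]
  ROSC2 <- pv[24L]; kdiff <- pv[25L]
  eGlc <- y[1L]
  w <- y[2L:10L]    # iGlc dGTP DNA wtCell ROS odGTP mDNA mCell cytVol
  ROSext <- y[11L]
  h <- y[12L:20L]
  monod <- if (eGlc > 0) eGlc / (eGlc + Ks) else 0
  upt_w <- U1 * w[4L] * monod
  upt_h <- U1 * h[4L] * monod

  block <- function(b, uptake, O3b) {
    iGlc <- b[1L]; dGTP <- b[2L]; DNA <- b[3L]; ROS <- b[5L]
    od <- b[6L]; mDNA <- b[7L]; cytVol <- b[9L]
    oxid <- dGTP * ROS * O2
    c(uptake / cytVol - Met1 * M1 * iGlc,
      M1 * iGlc - I1 * dGTP - oxid,
      I1 * dGTP + C2 * mDNA + S * mDNA + R1 * od - D1 * DNA,
      (D1 * DNA + R2 * mDNA) * cytVol,
      -oxid - O3b * ROS - kdiff * (ROS - ROSext),
      oxid - C1 * od - I2 * od - R1 * od,
      I2 * od - D2 * mDNA - C2 * mDNA - S * mDNA - R2 * mDNA,
      D2 * mDNA * cytVol,
      (D1 * DNA + R2 * mDNA) * cytVol * molML / GCperGen * CellVol)
  }
  free_vol <- 1 - w[9L] - h[9L]
  d <- numeric(20L)
  d[1L] <- -upt_w - upt_h
  d[2L:10L] <- block(w, upt_w, O3)
  d[11L] <- ROSC2 + w[9L] / free_vol * kdiff * (w[5L] - ROSext) +
    h[9L] / free_vol * kdiff * (h[5L] - ROSext)
  d[12L:20L] <- block(h, upt_h, 0)   # Hpx-: no AhpCF/KatEG sink
  d
}

# pad a named variant state to the fixed internal layout
.pad_state <- function(variant, state) {
  nm <- state_names(variant)
  if (!all(nm %in% names(state)))
    stop("state must contain components: ", paste(nm, collapse = ", "))
  state <- state[nm]
  if (variant$variant_id == "D_coculture") return(unname(state))
  y <- numeric(11L)
  names(y) <- c(.state_names_std, "ROSexternal")
  y[names(state)] <- state
  unname(y)
}

.unpad_deriv <- function(variant, d) {
  nm <- state_names(variant)
  if (variant$variant_id == "D_coculture") return(setNames(d, nm))
  full <- setNames(d, c(.state_names_std, "ROSexternal"))
  full[nm]
}

#' Right-hand side of a model variant
#'
#' Evaluates the time derivative of every state component for any variant,
#' implementing the printed equation set exactly, including the
#' culture-to-cytoplasm frame conversions (uptake flux divided by `cytVol`
#' entering the cytoplasm; DNA-completion fluxes multiplied by `cytVol`
#' leaving it; cytoplasmic-volume growth scaled by
#' `molML / GCperGen * CellVol`).
#'
#' @param variant A `variant_spec` or variant id.
#' @param t Time (s); the system is autonomous, so `t` is unused.
#' @param state Named state vector matching [state_names()].
#' @param params Baseline parameters; variant overrides and extras are
#'   applied internally.
#' @return Named vector of time derivatives, one per state component.
#' @examples
#' rhs("A", 0, initial_state("A", 3.1e-4))
#' @export
rhs <- function(variant, t = 0, state, params = baseline_parameters()) {
  variant <- .as_variant(variant)
  if (any(!is.finite(state)) || any(state < 0))
    stop("state components must be finite and non-negative")
  pv <- unname(.pack_parms(variant, params))
  y <- .pad_state(variant, state)
  d <- if (variant$variant_id == "D_coculture") .rhs_cocult_core(y, pv)
       else .rhs_mono_core(y, pv)
  .unpad_deriv(variant, d)
}

#' Population density in CFU per ml
#'
#' Converts the molar concentration of template-strand GC base pairs in the
#' 1 ml culture to a cell count: `(wtCell + mCell) * molML / GCperGen`.
#'
#' @param state Named state vector (or any vector with `wtCell` and `mCell`).
#' @param params Parameter set supplying `molML` and `GCperGen`.
#' @return Cells per ml.
#' @examples
#' density_cfu_per_ml(initial_state("A", 3.1e-4))
#' @export
density_cfu_per_ml <- function(state, params = baseline_parameters()) {
  wt <- state[["wtCell"]]
  mc <- if ("mCell" %in% names(state)) state[["mCell"]] else 0
  if (wt < 0 || mc < 0) stop("wtCell and mCell must be non-negative")
  (wt + mc) * params[["molML"]] / params[["GCperGen"]]
}

#' Cumulative mutation rate
#'
#' Ratio of mutated to total template base pairs, `mCell / (wtCell + mCell)`
#' — the chance of a base pair mutating in a single generation, accumulated
#' over the simulation so far.
#'
#' @param state Named state vector with `wtCell` and `mCell`.
#' @return Mutation rate per bp per generation.
#' @export
mutation_rate <- function(state) {
  wt <- state[["wtCell"]]; mc <- state[["mCell"]]
  tot <- wt + mc
  if (!is.finite(tot) || tot <= 0)
    stop("mutation rate undefined: wtCell + mCell must be positive")
  mc / tot
}
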