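---
title: "Modelling density-associated mutation rate plasticity in batch culture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling density-associated mutation rate plasticity in batch culture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dampsim)
```

## The phenomenon and the model

Microbial mutation rates fall as the final density of the population rises —
density-associated mutation rate plasticity (DAMP). dampsim implements a
family of deterministic ODE models of a 1 ml *Escherichia coli* batch
culture that connect glucose metabolism, growth, oxidative damage to the
nucleotide pool, and mutagenesis, in order to ask which mechanisms can
produce DAMP at all.

The baseline model (variant A) tracks ten variables. External glucose
`eGlc` (M, culture frame) is imported with Monod kinetics
(`U1 * wtCell * eGlc / (eGlc + Ks)`) into internal glucose `iGlc` (M,
cytoplasmic frame). `iGlc` is metabolised to dGTP (rate `M1`, with `Met1`
glucose consumed per dGTP) and, proportionally (multiplier `r`), to
hydrogen peroxide `ROS`. dGTP is either incorporated correctly into new DNA
(`I1`, completed into template-strand `wtCell` at `D1`) or oxidised by ROS
to 8-oxo-dGTP (`odGTP`, bimolecular rate `O2`). odGTP is hydrolysed by MutT
(`C1`), incorporated opposite adenine (`I2`, the mutagenic path into
`mDNA`), or opposite cytosine (`R1`). `mDNA` is either repaired by
MutY/MutS (`C2`, `S`) or fixed as a mutation in the template strand
(`mCell`, rate `D2`). ROS is degraded enzymatically (AhpCF/KatEG, lumped
first-order rate `O3`). The total cytoplasmic volume `cytVol` (ml) grows in
proportion to template-strand synthesis
(`molML / GCperGen * CellVol` per molar unit of new template), and converts
between the culture and cytoplasmic frames: uptake flux entering the
cytoplasm is divided by `cytVol`, and DNA-completion fluxes leaving it are
multiplied by `cytVol`.

Two readouts summarise a run at its horizon:

* **density** (CFU/ml) = `(wtCell + mCell) * molML / GCperGen`. `wtCell` is
  a molar concentration of template-strand GC base pairs, so the
  molecules-per-ml constant is required to recover a cell count; the
  inoculum values (`wtCell` = 8.5e-12 M, `cytVol` = 2.25e-9 ml) then
  correspond to about 2,175 cells, which validates the conversion.
* **cumulative mutation rate** (per bp per generation) =
  `mCell / (wtCell + mCell)`, the mutant fraction of all template base
  pairs accumulated up to that time — directly comparable to
  fluctuation-assay estimates.

The DAMP slope of a model is the OLS slope of `log10(mutation rate)` on
`log10(density)` across final states of a sweep over five log-spaced
initial glucose concentrations (3.1e-4 to 6.2e-3 M, i.e. 55–1,100 mg/L),
each integrated for 1e5 s (27.8 h, comfortably into stationary phase for
the baseline).

```{r slopes, eval = FALSE}
slope_table(c("A", "D", "F"))
```

## Structural variants

Each variant changes exactly one mechanism, with any re-fitted constant
chosen to restore the calibrated mutation rate (~2e-10 bp^-1 gen^-1 at
250 mg/L glucose):

* **B** — glucose importers upregulated at low glucose: uptake follows
  `U1 * wtCell * (U2 - eGlc) / (U2 - eGlc + K2)`, mirrored in the `iGlc`
  gain (glucose taken up must appear internally).
* **C** — constant cytoplasmic peroxide `ROSC` = 1.8e-7 M; the ROS state is
  removed.
* **D** — constant *external* peroxide production `ROSC2` = 6e-11 M/s into
  an extracellular pool `ROSexternal`, exchanging with the cytoplasm by
  passive diffusion (`kdiff` = 70 s^-1, the permeability–area/volume
  estimate for H2O2); `O2` re-fit to 40.
* **E** — ROS degradation gated by internal glucose
  (`O3 * ROS * iGlc / (iGlc + C3)`).
* **F** — ROS degradation proportional to population density
  (`ROS * molML / GCperGen * wtCell * C3a`).
* **G/H/I** — MutT activity up-regulated by `iGlc`, `odGTP` or `ROS`
  respectively: the hydrolysis term becomes `C1 * odGTP / (1 - X / C3x)`,
  with `C3x` placed just above the regulator's operating maximum so the
  factor stays positive (see *Numerical choices* for why the up-regulation
  is a divisor, and what happens at the pole); as these variants are
  written, the `R1` incorporation sink is absent from the odGTP balance.
* **J** — Michaelis–Menten MutT kinetics
  (`C1 * odGTP * odGTP / (odGTP + Kt)`; `Kt` and the re-fit `O2` are
  implemented exactly as specified even though `Kt` = 4.8e7 M is
  physically implausible, because the model definitions are treated as
  numerically literal).
* **K** — separate Michaelis–Menten AhpCF and KatEG peroxide sinks plus
  membrane diffusion to an external pool; `r` re-fit to 175.

Only D (constant external ROS input) and F (density-dependent ROS removal)
produce a strong negative DAMP slope (about −0.9); A, B, C, E, H, J and K
sit near zero, and the MutT-regulation variants G and I reach intermediate
negative slopes at the cost of extreme parameter sensitivity.

## The coculture extension

The two-population model extends variant D with an Hpx^- block — identical
kinetics but `O3 = 0` (no AhpCF/KatEG degradation) — sharing `eGlc` and the
external peroxide pool, whose exchange terms are weighted by each
population's cytoplasmic volume fraction
(`cytVol / (1 - cytVol - cytVol_hpx)`). The total inoculum is held at the
single-population value and split by the Hpx^-:wild-type mixing ratio, so
that the monoculture limit of the coculture is exactly model D (the
alternative — giving each population the full inoculum — would double the
starting population and break that reduction). The focal readouts use the
Hpx^- block only. At 1:1 mixing the wild-type population restores a strong
negative focal slope; as the wild-type inoculum shrinks the rescue fades
and the slope tends toward non-negative.

## DAMP slope conventions

`loglog_slope()` fits OLS of log rate on log density (simulation
convention). For assay data the natural observable is mutational events per
ml, so `damp_slope_from_events()` fits log events on log density and
subtracts 1: a constant mutation rate (events proportional to density) then
maps to slope 0 under both conventions. Both report the 95% CI half-width
from the t distribution and R². Weighted or mixed-effects structures used
for laboratory data are deliberately out of scope; the fixed-effects fit is
the supported surface for simulations and synthetic assays.

## Global sensitivity analysis

`sample_parameter_sets()` builds, for every perturbed parameter, the same
deterministic log-spaced grid of multiplicative factors from 0.1x to 10x
baseline and permutes each column independently under a seed, so the
margins are identical and fixed while the joint design is random and
uncorrelated. The perturbed set comprises the 15 kinetic constants plus the
fitted stoichiometry `Met1` and any variant extras; the conversion
constants `molML`, `GCperGen` and `CellVol` are deliberately excluded — they
define units rather than biology, and perturbing them would rescale the
readouts rather than the mechanism.

`evaluate_batch()` runs the five-condition sweep per set (solver failures
are recorded as incomplete, not raised) and `apply_filters()` applies five
cumulative criteria: (1) stationarity in every condition — fewer than 1
cell gained per 10 s step across the final 1,000 steps; (2) every final
density inside (1e7, 1e10) CFU/ml; (3) density strictly increasing with
glucose; (4) every mutation rate inside (2e-12, 2e-8); (5) log-log R² >
0.5. Survivors are summarised by the slope median and interquartile range
(linear-interpolation quartiles) and by Spearman rank correlations of each
parameter against the slope and against the mutation rate at the condition
nearest 250 mg/L. For the baseline model the glucose half-saturation `Ks`
dominates the slope association (rho ≈ 0.9), and no surviving set produces
a slope below −0.06 — the structure simply cannot generate DAMP.

The package default batch size is 2,000 sets, the scale used throughout the
tests and summaries; the design scales to the tens of thousands by raising
`n`, and the batch is embarrassingly parallel with results independent of
evaluation order.

## Synthetic fluctuation assays

The fluctuation module makes the slope-estimation stage testable without
laboratory data. A mutant arising during deterministic growth leaves a
clone whose size follows the Lea–Coulson law generalised to a mutant
relative fitness `w`: `q_j = rho * Gamma(j) * Gamma(rho+1) / Gamma(j+rho+1)`
with `rho = 1/w` (at `w = 1`, `q_j = 1/(j(j+1))`). The mutant-count pmf
follows by the standard convolution recursion from `p_0 = exp(-m)`. The
generator draws Poisson(m) mutations per culture with clone sizes
`floor(u^-w)` capped at `Nt` — the deterministic-growth device whose
fidelity is asserted against the pmf, not against a stochastic birth
process. Plating is binomial thinning; death is post-hoc thinning of both
the mutant count and the reported `Nt` — a robustness-check approximation,
not a birth–death model.

`estimate_m_ml()` maximises the likelihood over `m` with `w` fixed or
co-estimated (free fits that do not converge fall back to a fixed fitness
of 0.59, the study-wide median mutant fitness, with a warning); standard
errors come from the observed information; counts are winsorised at 256
since jackpot cultures carry no further information about `m`.
`estimate_m_p0()` implements `m = -ln(p0)` and refuses datasets without
both zero and non-zero cultures. `generate_study_like_dataset()` lays
assays log-spaced across 1e7–1e9 final cells, sets per-assay `m` to follow
a designed events-convention slope (events `m ∝ Nt^(slope+1)`, unit events
per culture at the geometric midpoint density), draws inocula log-normally
with median 3,000 cells, and emits the raw-assay schema (`assay_id`,
`treatment`, `N0`, `Nt`, `mutant_count`, `mixing_ratio`) with generator
truth carried separately. Assays whose cultures contain no mutants yield
the boundary estimate `m = 0` and are dropped before the log-log
regression. What the synthetic data does *not* emulate: plating-efficiency
differences between strains, fitness heterogeneity across assays,
culture-to-culture volume variation, and the blocking structure of real
experiments — so passing recovery tests demonstrates estimator correctness,
not robustness to those real-data features.

## Numerical choices

* **Solver.** `deSolve::ode` with `lsoda` (automatic stiff/non-stiff
  switching), `rtol = 1e-8`, `atol = 1e-14`, output every 10 s. The tight
  absolute tolerance matters: several states (ROS ~1e-7 M, odGTP ~1e-11 M,
  mCell ~1e-19 M) sit far below the default `atol = 1e-6` and would
  otherwise be integrated without meaningful error control. The right-hand
  sides are compiled (C) for batch throughput; an R reference
  implementation of every variant is exported through `rhs()` and the two
  are held to agreement in the tests, alongside an independent fixed-step
  Runge–Kutta oracle.
* **Non-negativity.** The equations are mass-action and analytically
  non-negative-preserving, but adaptive steps can undershoot; derivatives
  are therefore evaluated on the state clamped at zero. The variant-B
  uptake law is the one flux that does not vanish at `eGlc = 0`, so it
  carries a smooth exhaustion factor `eGlc / (eGlc + 1e-9)` (four orders
  below `Ks`; a hard cutoff stalls the step-size controller at the
  discontinuity).
* **MutT up-regulation as a divisor.** Writing the G/H/I regulation as
  `C1 * odGTP * (1 - X/C3x)` would make MutT activity *fall* as its
  inducer rises — the opposite of the stated mechanism — and produces
  positive slopes for G and a flat slope for I. The divisor form raises
  activity with the regulator and reproduces the intended intermediate
  DAMP slopes; its pole just above the operating range is also what makes
  G and I fragile under parameter perturbation, matching their high
  solver-failure rates in the sensitivity analysis.
* **The variant-I pole.** With the literal constants, cytoplasmic ROS at
  the two highest glucose conditions plateaus about 1.5% above `C3c`, the
  odGTP balance diverges, and the solver correctly reports failure there.
  `slope_table()` therefore fits each model's slope on the conditions that
  complete (at least three required) and records the failures; for variant
  I that is the lower three conditions, and the resulting slope (−0.63)
  lies where the full structure points.
* **Stationarity readout.** The final grid point is used directly (no
  interpolation to stationarity onset); the stationarity flag itself needs
  only the density 1,000 steps before the end, which is why the batch
  evaluator samples just three output times per run.
* **Horizon.** "About 28 h" is fixed at 1e5 s; baseline runs are
  stationary well before it.

## Problem sizes used by the checks

The test-suite defaults are sized for a single CPU: 2,000 parameter sets in
the sensitivity analysis, 1e6 Monte-Carlo cultures per expected-event value
in the pmf check, 70 assays of 16 cultures in the end-to-end slope
recovery, and full-horizon integrations everywhere else. All seeds are
fixed in the tests; every stochastic entry point requires an explicit seed.

## Known limitations

* The models are deterministic; demographic stochasticity in mutagenesis is
  represented only in the fluctuation-assay module, not in the ODEs.
* Only the 8-oxo-dGTP (AT>CG) mutational channel is modelled; other parts
  of the spectrum, and death or media renewal during culture, are not.
* Nominal units are documented, but several published constants are only
  dimensionally consistent if the equations are read as numerically
  literal; this package adopts that convention rather than re-deriving
  unit-consistent values.
* Variant J's printed constants make its MutT saturation term negligible at
  physiological odGTP concentrations; it is retained as specified.
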