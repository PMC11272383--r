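# dampsim

Dynamical models of **density-associated mutation rate plasticity (DAMP)**
— the inverse log-log relationship between the final density of a microbial
population and its mutation rate — in *Escherichia coli* batch culture.

The package is for researchers in microbial evolution and systems biology
who want to reproduce, probe or extend the ODE analysis behind this
phenotype: a ten-variable model coupling glucose uptake (Monod kinetics),
dGTP synthesis, oxidation of dGTP to 8-oxo-dGTP by hydrogen peroxide,
MutT/MutY/MutS sanitisation and repair, and growth of the population's
cytoplasmic volume. The central quantity is the DAMP slope

```
slope = d log10(mutation rate) / d log10(final density)
```

fitted by OLS across batch cultures started at five log-spaced glucose
concentrations (55–1,100 mg/L), where the cumulative mutation rate is
`mCell / (wtCell + mCell)` (mutant fraction of template base pairs) and
density is `(wtCell + mCell) * molML / GCperGen` (CFU/ml).

Eleven model structures (A–K) vary one mechanism each — glucose-importer
upregulation, constant internal or external peroxide, glucose-, density-,
substrate- or peroxide-regulated detoxification and MutT activity,
Michaelis–Menten kinetics — to ask which mechanisms can produce DAMP.
A two-population extension cocultures a peroxide-degradation-deficient
(Hpx^-) population with wild-type cells. A global sensitivity analysis
perturbs all kinetic parameters 0.1x–10x with independent shuffling,
filters the runs on five criteria and ranks parameters by Spearman
correlation with the slope. A synthetic fluctuation-assay module
(Lea–Coulson mutant-count distributions with a mutant-fitness parameter,
maximum-likelihood and p0 estimators of mutational events *m*) makes the
assay-side slope machinery testable end to end.

## Worked example

```r
library(dampsim)

slope_table(c("A", "D", "F"))
#>   variant      slope       ci95     r2 n
#> 1       A  0.0911033 0.05188361 0.9123 5
#> 2       D -0.9063800 0.01343650 0.9999 5
#> 3       F -0.8681311 0.03721497 0.9995 5
```

The baseline model A *reverses* DAMP (slope +0.09: denser cultures mutate
slightly more, because more glucose means more internal glucose and hence
more metabolic peroxide). Adding a constant external peroxide source with
membrane diffusion (model D) or making peroxide degradation proportional to
population density (model F) produces strong DAMP (slopes near −0.9),
comparable in magnitude to laboratory estimates for wild-type *E. coli*.

Calibration of the baseline at 250 mg/L glucose:

```r
traj <- integrate_model("A", eGlc0 = glucose_mgL_to_molar(250))
fin  <- unlist(tail(traj, 1)[-1])
density_cfu_per_ml(fin)   # 240025027  -> 2.4e8 CFU/ml
mutation_rate(fin)        # 2.081413e-10 per bp per generation
```

Sensitivity analysis and coculture rescue:

```r
batch  <- evaluate_batch("A", sample_parameter_sets(2000, seed = 101))
filt   <- apply_filters(batch)
filt$counts                    # survivors per filter stage
summarize_slopes(batch, filt)  # median 0.060, IQR (0.024, 0.132)
head(rank_correlations(batch, filt), 1)  # Ks, rho ~ 0.90

co <- run_coculture_sweep(mixing_ratios = c(1, 124))
coculture_slope_table(co)
#>   ratio    slope    ci95
#> 1     1 -0.89677 0.02436
#> 2   124 -0.15589 0.12465
```

At 1:1 mixing the wild type restores DAMP in the Hpx^- population; with a
vanishing wild-type inoculum the rescue fades.

Synthetic fluctuation assays:

```r
ds   <- generate_study_like_dataset(70, true_slope = -0.83, seed = 42)
mhat <- estimate_dataset_m(ds)
damp_slope_from_events(mhat$Nt, mhat$m_hat)$slope   # -0.851 (SE 0.026)
```

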