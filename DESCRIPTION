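Package: dampsim
Title: Dynamical Models of Density-Associated Mutation Rate Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary differential equation models of metabolism, growth and
    oxidative mutagenesis in Escherichia coli batch culture, used to study how
    mutation rates change with final population density (density-associated
    mutation rate plasticity, DAMP). Provides the baseline nucleotide-oxidation
    model and its structural variants (altered glucose uptake, constant
    external peroxide production, density-dependent peroxide degradation,
    glucose-, oxidised-nucleotide- and peroxide-regulated MutT activity,
    Michaelis-Menten sanitisation and detoxification kinetics), a two-population
    wild-type/Hpx- coculture extension, log-log slope estimation of the
    density-mutation rate relationship, a global parameter sensitivity analysis
    with five-stage filtering and Spearman rank summaries, and a synthetic
    Luria-Delbruck fluctuation-assay module with maximum-likelihood and p0
    mutation-rate estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
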