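Package: perfusionNE
Title: Nash-Equilibrium Modelling of Liver Machine Perfusion and Oxidative Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Game-theoretic (Nash-equilibrium) simulation of liver metabolism
    during organ preservation. Each enzymatic node of a compartmentalised
    metabolic network minimises its dimensionless Gibbs free energy subject to
    element and charge balances, and transport fluxes between nodes are
    converged by successive substitution. The package ships a reduced,
    thermodynamically self-consistent liver network (glycolysis, Krebs cycle
    with oxidative phosphorylation, purine degradation, superoxide/hydrogen
    peroxide/glutathione redox chemistry, fatty-acid and mevalonate synthesis),
    a static-cold-storage followed by machine-perfusion protocol engine with
    reactive-oxygen-species bookkeeping, Monte Carlo optimisation of gradual
    warming temperature policies, and Monte Carlo minimisation of glutathione
    supplementation keeping hydrogen peroxide in its physiological band.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
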