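Package: soilHRA
Title: Probabilistic Source-Oriented Health-Risk Assessment for
    Heavy-Metal-Contaminated Soil
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for probabilistic human health-risk assessment of
    heavy metals in topsoil. Couples receptor-model source apportionment
    (a constrained non-negative factorization of the sample-by-element
    concentration matrix) with the USEPA average-daily-dose exposure model
    for ingestion and dermal contact, and propagates parameter uncertainty
    by seeded Monte Carlo simulation to yield hazard-quotient/hazard-index
    and cancer-risk distributions for children, adult females, and adult
    males, both for whole-soil concentrations and resolved by pollution
    source. Includes a parametric distribution toolkit (beta-PERT,
    triangular, Gumbel-maximum, logistic, location-scale Student-t,
    percentile-parameterized normal and lognormal families with
    truncation), distribution fitting and AIC-based family selection, and
    a synthetic soil-survey generator with known latent source structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    fitdistrplus,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
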