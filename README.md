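# soilHRA

Probabilistic, source-oriented human health-risk assessment for
heavy-metal-contaminated topsoil.

Soil surveys measure total metal concentrations (here Zn, Cu, Cr, Pb, Hg,
mg/kg), but regulators need to know two further things: *how risky* those
levels are for people who live on the soil, and *which pollution sources*
carry the risk. `soilHRA` couples the two standard tools for those
questions —

1. **Receptor-model source apportionment.** The sample-by-element matrix
   `X` is decomposed as a non-negative mixture of `k` latent sources,
   `X ≈ G P` (`G`: site-by-source contributions, `P`: source-by-element
   compositions), by multiplicative-update non-negative matrix
   factorization with restarts, reported with per-element R² and a
   singular-value signal-to-noise diagnostic. The fraction tensor
   `F[i,j,k] = G[i,k]P[k,j] / Σ_κ G[i,κ]P[κ,j]` then splits each measured
   value into per-source concentrations `C^k = F^k ⊙ X` that sum back to
   `X` exactly. Published loading percentages can be injected directly via
   `externalCompositionModel()`.

2. **USEPA dose–response risk model with Monte Carlo uncertainty.**
   For each population (children, adult females, adult males) the average
   daily dose from incidental ingestion and dermal contact is

       ADD_ing    = C · IR · CF · EF · ED / (BW · AT)
       ADD_dermal = C · CF · SA · AF · ABF · EF · ED / (BW · AT)

   with AT = 365·ED days for the noncarcinogenic endpoint (ED cancels;
   the reduced form is implemented) and AT = 25 550 days for the
   carcinogenic endpoint. Noncarcinogenic risk is the hazard index
   HI = Σ ADD/RfD (acceptable below 1); carcinogenic risk is
   TCR = Σ ADD·SF (acceptable below 10⁻⁶, unacceptable above 10⁻⁴).
   Exposure parameters are sampled from their published distributions
   (lognormal body weight and ingestion rate, percentile-parameterized
   normal skin area, beta-PERT adherence, triangular exposure frequency,
   uniform duration) over seeded 10 000-iteration simulations; per-source
   concentrations can themselves be sampled from fitted distributions
   (location-scale Student-t, logistic, Gumbel-max).

A distribution toolkit (`distSpec`, `drawSamples`, `fitSpec`,
`selectBestFit`) supplies every parameterization the exposure tables use,
with truncation by rejection sampling and AIC/Kolmogorov–Smirnov family
selection, and a synthetic-survey generator (`generateSurvey`,
`emulateStudy`) produces 170-site tables with known latent source
structure so the whole pipeline is testable without field data.

## Worked example

```r
library(soilHRA)

# a synthetic survey calibrated to the study area's descriptive statistics
survey <- emulateStudy(seed = 1)
describeTable(survey$table)[, c("mean", "cv", "meanToBackground")]
#>      mean    cv meanToBackground
#> Zn 54.875 0.277            0.798
#> Cu 26.841 0.386            1.005
#> Cr 36.512 0.287            0.741
#> Pb 79.331 0.235            4.089
#> Hg  0.030 0.342            1.763
```

Pb sits at ~4.1× the regional background and Hg at ~1.8×, while Zn and Cr
stay below background — the enrichment pattern that motivates a
source-resolved assessment.

```r
# whole-soil probabilistic risk for children at the published mean
# concentrations
risk <- runConcentrationHRA(studyConcentrations(),
                            exposureFactors("children"),
                            nIter = 10000, seed = 1)
risk
#> RiskResult [concentration mode] children / total: 10000 iterations (seed 1)
#>   mean HI  = 0.2114   P(HI > 1)      = 0.0000
#>   mean TCR = 4.384e-06   P(TCR > 1e-6)  = 0.8624   P(TCR > 1e-4) = 0.0000
```

The mean hazard index (0.21) is well below 1 — no appreciable
noncarcinogenic risk — but the mean total carcinogenic risk (4.4 × 10⁻⁶)
exceeds the 10⁻⁶ acceptability threshold in ~86% of iterations.

```r
# which source carries that cancer risk? sample each source's fitted
# concentration distributions under shared exposure draws
src <- runSourceHRA(sourceProfileSpecs(), exposureFactors("children"),
                    nIter = 10000, seed = 1)
signif(sapply(src[1:4], function(r) riskSummary(r)$TCR$mean), 3)
#>  factor1  factor2  factor3  factor4
#> 7.39e-08 4.73e-07 1.45e-06 2.52e-06
round(sourceContributionShares(src), 1)
#> factor1 factor2 factor3 factor4
#>     1.6    10.5    32.2    55.7
```

The industrial-type source (factor 4) alone exceeds the 10⁻⁶ threshold
(mean CR 2.5 × 10⁻⁶) and contributes ~56% of the combined carcinogenic
risk, with the coal-type source (factor 3) second — the Cr-driven pattern
that makes those two sources the priority control targets.

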