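---
title: "Methods: probabilistic source-oriented health-risk assessment for soil heavy metals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic source-oriented health-risk assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilHRA)
```

# The model

`soilHRA` implements a three-stage pipeline for heavy-metal-contaminated
topsoil: receptor-model source apportionment, source-resolved
concentration splitting, and Monte Carlo propagation of exposure-parameter
uncertainty through the USEPA dose–response model.

## Source apportionment

The receptor-model premise is that measured concentrations are linear
mixtures of a small number of sources:

$$ C_{ij} \;=\; \sum_{k=1}^{K} G_{ik}\,p_{kj} + e_{ij}, $$

with non-negative contributions $G$ (site × source) and compositions $P$
(source × element). `factorizeSources()` estimates $G$ and $P$ by
multiplicative-update non-negative matrix factorization (Frobenius
objective) with several random restarts, keeping the best run. Two
numerical choices matter:

* **Column scaling.** The raw Frobenius objective would be dominated by
  the major elements (Pb at ~80 mg/kg versus Hg at ~0.03 mg/kg), so the
  factorization runs on the column-mean-scaled table — equivalent to
  minimizing relative rather than absolute reconstruction error — and the
  composition matrix is rescaled back afterwards. Per-element R² is
  unaffected by this choice (it is scale-invariant per column).
* **Scale and order fixing.** $GP = (Gc)(P/c)$ for any positive diagonal
  $c$, so each composition row is normalized to sum to one with the scale
  absorbed into $G$, and sources are ordered by decreasing total
  contribution. This makes output deterministic for a fixed seed.

Diagnostics follow receptor-model practice: per-element centered R², and
a signal-to-noise surrogate defined as the ratio of the $k$-th to the
$(k{+}1)$-th singular value of the column-standardized table. The
conventional acceptance rule (min R² ≥ 0.8, S/N ≥ 2) is a configurable
*warning*, not an error: a weak model should be visible, not fatal. The
S/N surrogate is deliberately simple and is not numerically identical to
the statistic reported by the proprietary EPA Unmix screens it stands in
for; it captures the same question — is there a $k$-dimensional signal
above the noise floor?

Identifiability deserves a frank caveat. Non-negative factorizations are
unique (up to source permutation) only when the data contain near-pure
rows or columns. Surveys whose source contributions are tightly
distributed around their means admit a cone of equivalent rotated
solutions, and no algorithm can pin down the "true" compositions from
such data; recovered compositions should then be read as one admissible
basis. The package's recovery tests use dispersed contributions
(coefficient of variation ≥ 0.8), where recovery is reliable.

An optional pre-screen (`dropOutliers = TRUE`) removes sites with any
element beyond its mean ± 3 sd before factorization, a common
receptor-model practice; it is off by default because the appropriate
outlier rule is survey-specific.

Because the hybrid risk model only needs the *fraction* of each
measurement attributable to each source, a second entry point,
`externalCompositionModel()`, builds the fraction tensor directly from
published percent loadings applied uniformly to all samples. Each
element's percentages must sum to ≤ 100; any remainder becomes an
explicit "unattributed" source so the mass balance
$\sum_k C^k_{ij} = X_{ij}$ always holds. Both readings of the hybrid
model — sample-specific fractions from a fitted factorization, or
constant published loadings — are therefore available.

## Dose and risk

For each population group the two retained pathways are incidental soil
ingestion and dermal contact (inhalation is omitted: resuspended soil
contributes negligibly compared with these two):

$$ ADD_{ing} = \frac{C \cdot IR \cdot CF \cdot EF \cdot ED}{BW \cdot AT},
\qquad
ADD_{derm} = \frac{C \cdot CF \cdot SA \cdot AF \cdot ABF \cdot EF \cdot ED}{BW \cdot AT}. $$

The averaging time differs by endpoint, and that difference is treated
algebraically, not numerically: for the noncarcinogenic endpoint
$AT = 365 \cdot ED$ days, so $ED$ cancels and the implementation uses the
reduced form $C \cdot IR \cdot CF \cdot EF/(BW \cdot 365)$ — a zero
exposure-duration draw can never produce 0/0, and noncarcinogenic hazard
is exactly invariant to $ED$ (a tested property). For the carcinogenic
endpoint $AT = 365 \times 70 = 25550$ days and $ED$ stays explicit.
Hazard quotients divide dose by the pathway-specific reference dose and
sum to the hazard index HI (bands: < 1 acceptable, 1–4 moderate, ≥ 4
high, closed on the left since the published strict inequalities leave
the boundaries undefined); cancer risks multiply dose by the pathway
slope factor and sum to TCR (bands: < 10⁻⁶ acceptable, 10⁻⁶–10⁻⁴
tolerable, > 10⁻⁴ unacceptable). Pathways without a slope factor
contribute exactly zero — only Cr (both pathways) and Pb (oral only)
carry cancer slopes among the five metals.

### The two dermal conventions

The published exposure-parameter table is internally ambiguous on the
carcinogenic dermal pathway, and the package resolves the ambiguity by
making both readings first-class configuration, with defaults chosen for
consistency with the published risk magnitudes:

* **Absorption fraction (ABF).** The table lists 0.001 for the
  noncarcinogenic and 0.01 for the carcinogenic endpoint, but forward
  calculation with 0.01 overshoots every published carcinogenic-risk
  value several-fold, while 0.001 lands near them. Default:
  `abfCarcinogenic = 0.001`; the tabulated literal is available via
  `exposureFactors(abfCarcinogenic = 0.01)`.
* **Adherence factor (AF).** AF is tabulated as beta-PERT
  (mode 0.2, range 0–3.3 for children). The PERT *mean* (≈ 0.68) is 3.4×
  its mode, and published carcinogenic risks are most consistent with the
  most-likely value; the carcinogenic pathway therefore uses the mode by
  default (`afCarcinogenic = "point"`), while the noncarcinogenic pathway
  always samples the full PERT. `afCarcinogenic = "pert"` switches the
  carcinogenic pathway to full sampling.

Every result object embeds a fingerprint of the complete configuration,
so outputs produced under different conventions cannot be silently mixed.

## Monte Carlo engine

Each iteration draws one value per exposure parameter per population
(parameters are population-level, shared across elements and pathways
within the iteration) and one concentration per element; 10 000
iterations is the default, at which the running means are stable to well
under 1% (`convergenceReport()` checks this with a √n standard-error
scaling that is itself property-tested). Three concentration input modes
are supported: empirical resampling of table rows, per-element fitted
distributions, and point means. Replication runs use point means — the
only whole-soil concentration information published — so their spread
reflects exposure-parameter uncertainty alone.

Source-oriented runs share one set of exposure draws across all sources.
With per-source tables from a mass-conserving decomposition the same
resampled row indices are also shared, which makes per-source risk draws
sum *exactly* (to floating-point) to the whole-soil draws — a tested
invariant. With per-source fitted distributions the concentration draws
are independent across sources, matching the published workflow.

Reproducibility choices: all sampling flows from a single integer seed;
population and source runs inside `replicateStudy()` use sub-seeds
derived by a fixed linear rule (`(seed · 48271 + 7919 · offset) mod
2147483629`) so runs are independent but jointly reproducible; summary
percentiles use the nearest-rank method (the value at sorted position
⌈p·n⌉), which is exact on constant draws and needs no interpolation
convention.

# Distribution toolkit

The exposure tables use several parameterizations that stock R functions
do not expose directly, so `distSpec()` validates and stores each family
in its tabulated form:

| family | parameters | notes |
|---|---|---|
| `point` | value | degenerate |
| `uniform` | min, max | ED |
| `triangular` | min, mode, max | EF; inverse-CDF sampling |
| `normal_p50_p95` | p50, p95 | SA; sd = (p95 − p50)/1.6449 |
| `lognormal_mean_sd` | arithmetic mean, sd | BW |
| `lognormal_p50_p95` | p50, p95 | IR; σ = ln(p95/p50)/1.6449 |
| `beta_pert` | min, mode, max (λ = 4) | AF |
| `student_t_loc_scale` | midpoint, scale (df = 5) | fitted source concentrations |
| `logistic` | mean, scale | fitted source concentrations |
| `gumbel_max` | likeliest, scale | fitted source concentrations |

Fixed numerical conventions: the 95th-percentile z-score is 1.6449
everywhere (a convention, not a tuning knob); the beta-PERT shape
parameter defaults to the classical λ = 4 and is accepted as an optional
parameter. The
published Student-t fits omit degrees of freedom, which the original
fitting software does not print; the package fixes df = 5 by default and
exposes it (`sourceProfileSpecs(df = )`) so sensitivity can be checked —
the location-scale Student-t mean is its midpoint for any df > 1, so the
replication means are insensitive to this choice. Zero-scale
location-scale entries (e.g. a tabulated logistic "(0.02, 0.00)") degrade
to point masses rather than erroring.

Concentration distributions with unbounded support (Student-t, logistic,
Gumbel) are truncated below at zero by default: concentrations are
physical quantities, and the source-profile locations sit close enough to
zero (e.g. logistic mean 4.07, scale 0.63) that the negative tail is not
always negligible. Truncation is enforced by rejection resampling, never
clipping, so the in-bounds distribution is the exact conditional law and
no probability mass piles up at the bound; a truncation that excludes
essentially all mass (acceptance < 10⁻⁴) raises an error rather than
looping. Whether the original study truncated its sampled parameters is
not recorded anywhere; runs therefore carry the truncation policy in
their configuration fingerprint so any discrepancy is attributable.
Untruncated means use closed forms (tested against 10⁶-draw sample
means); truncated means are estimated by sampling and flagged
`approximate`.

Fitting (`fitSpec`) is maximum likelihood via `fitdistrplus` for normal,
lognormal and logistic; direct optimization with hand-written
log-densities for Gumbel-max and fixed-df location-scale Student-t (no
stock fitter exists for either in the tabulated parameterization); the
closed-form MLE (sample range) for uniform; and a method-of-moments
fallback for triangular (range endpoints, mode = 3·mean − min − max
clamped), since the triangular MLE is notoriously unstable in the
endpoints. `selectBestFit` ranks candidates by AIC with
Kolmogorov–Smirnov, then enum-order tie-breaks — the batch-fit behavior
of commercial risk tools. Constant data degrade to a point spec.

# The synthetic survey generator

`generateSurvey()` emulates the *structure* of a regional topsoil
survey: `X = (G P) ⊙ (1 + ε)`, with lognormal source contributions
(non-negative and right-skewed, as field concentrations are), composition
rows derived from percent loadings and target element means, and
zero-mean multiplicative noise (entries clipped at zero, with clips
counted). Defaults are the study conditions: 170 sites, five elements,
four sources, 5% noise, target means (55.34, 27.16, 37.31, 79.60, 0.03)
mg/kg.

`emulateStudy()` additionally calibrates the per-source contribution CVs
by non-negative least squares from the independent-mixture variance
identity $CV_j^2 \approx \sum_k w_{kj}^2 cv_k^2 + noise_j^2$ so that
generated marginal CVs approach the published (0.22, 0.36, 0.28, 0.24,
0.28). One structural fact forces a compromise: Zn and Cu have nearly
identical source-share vectors in the published loadings but very
different CVs, which no assignment of independent per-source variances
can reproduce. The residual per-element variance is therefore assigned to
element-specific noise — Cu ends up with ~0.29 effective noise against
the 0.05 floor of the other elements. Consequently factorization of
`emulateStudy()` output recovers Cu's composition less faithfully than
the others; recovery properties are instead tested on homogeneous-noise
`generateSurvey()` output, which is what the generator's own contract
promises.

What passing tests on synthetic data do *not* show: the generator has no
spatial autocorrelation, no censored below-detection values, no
correlated source contributions, and exact lognormality — all departures
real surveys exhibit. Range targets are checked only loosely (±25% of the
published min/max) since the site-level data behind them are unreleased.
The site count defaults to 170 (the campaign is variously reported as 170
or 171 samples) and is exposed.

# Replication configuration and problem sizes

`replicateStudy()` and `scripts/acceptance.R` run: whole-soil Monte Carlo
risk for children, adult females and adult males at the published mean
concentrations with full exposure distributions, and the children's
source-oriented run from the published per-source concentration fits —
each at 10 000 iterations (vectorized; well under a second per run). The
test suite sizes its simulations to what each check needs: 10⁶ draws for
moment closed forms, 5 000 observations for fit recovery (bounds from
asymptotic standard errors), 170 × 5 tables with 5–8 restarts for
factorization recovery, 100 replicates of n = 2000 for family-selection
accuracy.

One published input deserves flagging: the factor-3 Pb fit is tabulated
with likeliest value 111.29 mg/kg, which is inconsistent with the same
study's loading matrix (16% of a 79.6 mg/kg mean ≈ 12.7 mg/kg) and with
the published factor-3 hazard index; it looks like a decimal slip. The
package ships the tabulated literal — `sourceProfileSpecs()` is a
transcription, not a correction — and the factor-3 *cancer* risk, which
is Cr-dominated, is insensitive to it; factor-3 hazard-index comparisons
should be read with this in mind.

# Known limitations

* The factorization is a surrogate for the proprietary Unmix/SAFER
  algorithm with the same input/output contract, not a reimplementation;
  its S/N diagnostic is analogous, not identical.
* Exposure parameters are sampled independently (no copulas), as in the
  source workflow; correlated parameters (e.g. body weight with skin
  area) would tighten the risk distributions.
* No bioaccessibility adjustment, age-integrated lifetime risk, dietary
  pathways, or As/Cd coverage.
* Risk-band boundaries follow the closed-on-the-left convention stated
  above; published strict inequalities leave them undefined.
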