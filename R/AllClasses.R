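#' @import methods
NULL

# z-score of the 95th percentile used throughout the percentile
# parameterizations (fixed, not recomputed, for reproducibility)
.Z95 <- 1.6449
# Euler-Mascheroni constant (Gumbel-max mean)
.EULER_GAMMA <- 0.5772156649015329

.DIST_FAMILIES <- c(
  "point", "uniform", "triangular", "normal_p50_p95", "lognormal_mean_sd",
  "lognormal_p50_p95", "beta_pert", "student_t_loc_scale", "logistic",
  "gumbel_max"
)

.DIST_PARAMS <- list(
  point               = "value",
  uniform             = c("min", "max"),
  triangular          = c("min", "mode", "max"),
  normal_p50_p95      = c("p50", "p95"),
  lognormal_mean_sd   = c("mean", "sd"),
  lognormal_p50_p95   = c("p50", "p95"),
  beta_pert           = c("min", "mode", "max"),
  student_t_loc_scale = c("midpoint", "scale"),
  logistic            = c("mean", "scale"),
  gumbel_max          = c("likeliest", "scale")
)

# optional parameters with defaults, per family
.DIST_OPTIONAL <- list(
  beta_pert           = c(lambda = 4),
  student_t_loc_scale = c(df = 5)
)

#' Parametric distribution specification
#'
#' A validated, tagged parametric distribution in one of the
#' parameterizations used for soil exposure and source-concentration
#' inputs: point mass, uniform, triangular (most-likely/min/max), normal
#' given 50th/95th percentiles, lognormal given arithmetic mean/sd or
#' 50th/95th percentiles, beta-PERT, location-scale Student-t, logistic,
#' and Gumbel maximum-extreme-value. Optional lower/upper truncation
#' bounds restrict the support; sampling under truncation is by rejection
#' so the in-bounds shape is the exact conditional distribution.
#'
#' Use [distSpec()] to construct instances; direct slot access is
#' discouraged.
#'
#' @slot family character(1), one of the supported family tags.
#' @slot params named numeric vector of family parameters.
#' @slot lowerTrunc numeric(1) lower truncation bound (`-Inf` if unset).
#' @slot upperTrunc numeric(1) upper truncation bound (`Inf` if unset).
#' @seealso [distSpec()], [drawSamples()], [fitSpec()], [selectBestFit()]
#' @export
setClass("DistributionSpec",
  representation(
    family = "character",
    params = "numeric",
    lowerTrunc = "numeric",
    upperTrunc = "numeric"
  ),
  prototype(
    family = "point",
    params = c(value = 0),
    lowerTrunc = -Inf,
    upperTrunc = Inf
  )
)

setValidity("DistributionSpec", function(object) {
  fam <- object@family
  if (length(fam) != 1L || !fam %in% .DIST_FAMILIES) {
    return(sprintf("unknown family '%s'", paste(fam, collapse = ",")))
  }
  p <- object@params
  req <- .DIST_PARAMS[[fam]]
  opt <- names(.DIST_OPTIONAL[[fam]])
  missing <- setdiff(req, names(p))
  if (length(missing)) {
    return(sprintf("family '%s': missing parameter(s) %s", fam,
                   paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(p), c(req, opt))
  if (length(extra)) {
    return(sprintf("family '%s': unknown parameter(s) %s", fam,
                   paste(extra, collapse = ", ")))
  }
  if (anyNA(p) || any(!is.finite(p))) return("parameters must be finite")
  msg <- switch(fam,
    uniform = if (p[["min"]] >= p[["max"]]) "min < max violated",
    triangular = ,
    beta_pert = {
      if (p[["min"]] >= p[["max"]]) "min < max violated"
      else if (p[["mode"]] < p[["min"]] || p[["mode"]] > p[["max"]])
        "min <= mode <= max violated"
    },
    normal_p50_p95 = if (p[["p95"]] <= p[["p50"]]) "p95 > p50 violated",
    lognormal_p50_p95 = {
      if (p[["p50"]] <= 0) "p50 > 0 violated"
      else if (p[["p95"]] <= p[["p50"]]) "p95 > p50 violated"
    },
    lognormal_mean_sd = {
      if (p[["mean"]] <= 0) "mean > 0 violated"
      else if (p[["sd"]] <= 0) "sd > 0 violated"
    },
    student_t_loc_scale = ,
    logistic = ,
    gumbel_max = if (p[["scale"]] < 0) "scale >= 0 violated",
    NULL
  )
  if (!is.null(msg) && is.character(msg)) return(msg)
  if (length(object@lowerTrunc) != 1L || length(object@upperTrunc) != 1L) {
    return("truncation bounds must be scalars")
  }
  if (object@lowerTrunc >= object@upperTrunc) {
    return("lower_trunc < upper_trunc violated")
  }
  TRUE
})

#' @describeIn DistributionSpec compact one-line display.
#' @param object a `DistributionSpec`.
#' @export
setMethod("show", "DistributionSpec", function(object) {
  pars <- paste(sprintf("%s=%g", names(object@params), object@params),
                collapse = ", ")
  tr <- ""
  if (is.finite(object@lowerTrunc) || is.finite(object@upperTrunc)) {
    tr <- sprintf(" truncated to [%g, %g]", object@lowerTrunc,
                  object@upperTrunc)
  }
  cat(sprintf("DistributionSpec: %s(%s)%s\n", object@family, pars, tr))
  invisible(object)
})

#' Source apportionment model
#'
#' Result of the constrained non-negative factorization of a
#' sample-by-element concentration table into `k` latent pollution
#' sources: a non-negative contribution matrix `G` (samples x sources)
#' and a non-negative composition matrix `P` (sources x elements), with
#' per-element coefficient-of-determination diagnostics and a
#' signal-to-noise surrogate (ratio of the k-th to the (k+1)-th singular
#' value of the column-standardized table).
#'
#' @slot G numeric matrix, n samples x k sources, non-negative.
#' @slot P numeric matrix, k sources x m elements, non-negative; each row
#'   sums to the mean concentration scale absorbed from `G`
#'   normalization (rows of `P` are normalized to sum to 1 and the scale
#'   moved into `G`).
#' @slot perElementR2 named numeric, centered R-squared per element.
#' @slot estimatedSN numeric(1), singular-value ratio diagnostic.
#' @slot nSources integer(1).
#' @slot seed integer(1) seed used for the restarts.
#' @slot converged logical(1).
#' @seealso [factorizeSources()], [contributionFractions()]
#' @export
setClass("SourceModel",
  representation(
    G = "matrix",
    P = "matrix",
    perElementR2 = "numeric",
    estimatedSN = "numeric",
    nSources = "integer",
    seed = "integer",
    converged = "logical"
  )
)

setValidity("SourceModel", function(object) {
  if (any(object@G < 0)) return("G has negative entries")
  if (any(object@P < 0)) return("P has negative entries")
  if (ncol(object@G) != nrow(object@P)) return("G/P dimension mismatch")
  if (ncol(object@G) != object@nSources) return("nSources mismatch")
  if (any(object@perElementR2 > 1 + 1e-12)) return("R2 above 1")
  TRUE
})

#' @describeIn SourceModel display dimensions and diagnostics.
#' @param object a `SourceModel`.
#' @export
setMethod("show", "SourceModel", function(object) {
  cat(sprintf(
    "SourceModel: %d samples x %d elements, k = %d source(s)\n",
    nrow(object@G), ncol(object@P), object@nSources))
  cat(sprintf("  converged: %s (seed %d)\n", object@converged, object@seed))
  cat(sprintf("  min per-element R2: %.4f   S/N surrogate: %.3f\n",
              min(object@perElementR2), object@estimatedSN))
  invisible(object)
})

#' Per-sample per-element source fractions
#'
#' The fraction tensor `F[i, j, k]` giving, for sample `i` and element
#' `j`, the share of the measured concentration attributed to source
#' `k`, together with the population-level percent share of each element
#' carried by each source (`elementShare`, sources x elements, columns
#' summing to 100).
#'
#' @slot fractions 3-d numeric array, samples x elements x sources, in
#'   `[0, 1]`.
#' @slot elementShare numeric matrix, sources x elements, percent.
#' @seealso [contributionFractions()], [sourceConcentrations()],
#'   [externalCompositionModel()]
#' @export
setClass("ContributionFractions",
  representation(
    fractions = "array",
    elementShare = "matrix"
  )
)

setValidity("ContributionFractions", function(object) {
  f <- object@fractions
  if (length(dim(f)) != 3L) return("fractions must be a 3-d array")
  if (any(f < -1e-12) || any(f > 1 + 1e-12)) {
    return("fractions outside [0, 1]")
  }
  cs <- colSums(object@elementShare)
  if (any(abs(cs - 100) > 1e-6)) {
    return("elementShare columns must sum to 100")
  }
  TRUE
})

#' @describeIn ContributionFractions display tensor dimensions and shares.
#' @param object a `ContributionFractions`.
#' @export
setMethod("show", "ContributionFractions", function(object) {
  d <- dim(object@fractions)
  cat(sprintf(
    "ContributionFractions: %d samples x %d elements x %d sources\n",
    d[1], d[2], d[3]))
  cat("element shares (%):\n")
  print(round(object@elementShare, 1))
  invisible(object)
})

#' Population exposure-factor set
#'
#' The per-population exposure parameters of the USEPA average-daily-dose
#' model as distribution specifications: body weight BW (kg), exposure
#' duration ED (years), exposed skin area SA (cm^2), soil-to-skin
#' adherence factor AF (mg/(cm^2 d)), soil ingestion rate IR (mg/day) and
#' exposure frequency EF (days/year), plus the point-valued dermal
#' absorption fractions (noncarcinogenic and carcinogenic endpoints) and
#' the mg-to-kg conversion factor CF = 1e-6. Averaging time follows the
#' endpoint: 365 x ED days for the noncarcinogenic endpoint (so ED
#' cancels from the dose) and 365 x 70 = 25550 days for the carcinogenic
#' endpoint.
#'
#' @slot population character(1): "children", "female" or "male".
#' @slot BW,ED,SA,AF,IRing,EF `DistributionSpec` objects.
#' @slot abfNoncarcinogenic,abfCarcinogenic numeric(1) dermal absorption.
#' @slot cf numeric(1), fixed at 1e-6 kg/mg.
#' @slot afCarcinogenic character(1), "point" to use the most-likely
#'   adherence value for the carcinogenic pathway or "pert" to sample the
#'   full beta-PERT (the noncarcinogenic pathway always samples the PERT).
#' @seealso [exposureFactors()], [drawExposure()]
#' @export
setClass("ExposureFactors",
  representation(
    population = "character",
    BW = "DistributionSpec",
    ED = "DistributionSpec",
    SA = "DistributionSpec",
    AF = "DistributionSpec",
    IRing = "DistributionSpec",
    EF = "DistributionSpec",
    abfNoncarcinogenic = "numeric",
    abfCarcinogenic = "numeric",
    cf = "numeric",
    afCarcinogenic = "character"
  )
)

setValidity("ExposureFactors", function(object) {
  if (!object@population %in% c("children", "female", "male")) {
    return("population must be children, female or male")
  }
  if (object@cf != 1e-6) return("CF must be exactly 1e-6 kg/mg")
  if (object@abfNoncarcinogenic <= 0 || object@abfCarcinogenic <= 0) {
    return("absorption fractions must be positive")
  }
  if (!object@afCarcinogenic %in% c("point", "pert")) {
    return("afCarcinogenic must be 'point' or 'pert'")
  }
  TRUE
})

#' @describeIn ExposureFactors display the parameter set.
#' @param object an `ExposureFactors`.
#' @export
setMethod("show", "ExposureFactors", function(object) {
  cat(sprintf("ExposureFactors for %s\n", object@population))
  for (s in c("BW", "ED", "SA", "AF", "IRing", "EF")) {
    sp <- slot(object, s)
    cat(sprintf("  %-6s %s(%s)\n", s, sp@family,
                paste(sprintf("%g", sp@params), collapse = ", ")))
  }
  cat(sprintf("  ABF    %g (noncarcinogenic), %g (carcinogenic)\n",
              object@abfNoncarcinogenic, object@abfCarcinogenic))
  cat(sprintf("  AF carcinogenic variant: %s\n", object@afCarcinogenic))
  invisible(object)
})

#' Monte Carlo risk-simulation result
#'
#' Per-iteration draws of the hazard index (HI, noncarcinogenic) and
#' total carcinogenic risk (TCR) for one population and one input mode,
#' with a summary (mean, sd, nearest-rank percentiles, exceedance
#' probabilities) recomputable from the draws, and a fingerprint of the
#' configuration that produced them.
#'
#' @slot population character(1).
#' @slot mode character(1), "concentration" or "source".
#' @slot label character(1), source label or "total".
#' @slot nIter integer(1).
#' @slot seed integer(1).
#' @slot draws data.frame with numeric columns `HI` and `TCR` (one row
#'   per iteration).
#' @slot components list of per-element draw matrices (`HQ`, `CR`).
#' @slot summary list, see [summarizeRisk()].
#' @slot configFingerprint character(1).
#' @seealso [runConcentrationHRA()], [runSourceHRA()], [summarizeRisk()]
#' @export
setClass("RiskResult",
  representation(
    population = "character",
    mode = "character",
    label = "character",
    nIter = "integer",
    seed = "integer",
    draws = "data.frame",
    components = "list",
    summary = "list",
    configFingerprint = "character"
  )
)

setValidity("RiskResult", function(object) {
  if (!all(c("HI", "TCR") %in% names(object@draws))) {
    return("draws must contain HI and TCR columns")
  }
  if (nrow(object@draws) != object@nIter) return("nIter/draws mismatch")
  TRUE
})

#' @describeIn RiskResult display the summary.
#' @param object a `RiskResult`.
#' @export
setMethod("show", "RiskResult", function(object) {
  s <- object@summary
  cat(sprintf("RiskResult [%s mode] %s / %s: %d iterations (seed %d)\n",
              object@mode, object@population, object@label,
              object@nIter, object@seed))
  cat(sprintf("  mean HI  = %.4g   P(HI > 1)      = %.4f\n",
              s$HI$mean, s$HI$exceedance))
  cat(sprintf("  mean TCR = %.4g   P(TCR > 1e-6)  = %.4f   P(TCR > 1e-4) = %.4f\n",
              s$TCR$mean, s$TCR$exceedance1e6, s$TCR$exceedance1e4))
  invisible(object)
})
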