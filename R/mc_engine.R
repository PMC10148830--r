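# 31-polynomial rolling hash over the JSON form of a configuration:
# a run fingerprint (not cryptographic) embedded in results so that two
# runs are comparable only when their full configuration matches.
.configFingerprint <- function(config) {
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(txt))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# nearest-rank percentile: value at position ceiling(p/100 * n) of the
# sorted draws
.nearestRank <- function(x, probs) {
  s <- sort(x)
  n <- length(s)
  out <- s[pmax(1L, ceiling(probs / 100 * n))]
  names(out) <- paste0("p", probs)
  out
}

.summaryFromDraws <- function(draws) {
  list(
    HI = list(
      mean = mean(draws$HI), sd = sd(draws$HI),
      percentiles = .nearestRank(draws$HI, c(5, 25, 50, 75, 95)),
      exceedance = mean(draws$HI > 1)
    ),
    TCR = list(
      mean = mean(draws$TCR), sd = sd(draws$TCR),
      percentiles = .nearestRank(draws$TCR, c(5, 25, 50, 75, 95)),
      exceedance1e6 = mean(draws$TCR > 1e-6),
      exceedance1e4 = mean(draws$TCR > 1e-4)
    )
  )
}

# concentration draw matrix (nIter x elements) from one of the three
# input modes: empirical table resampling, per-element specs, point means
.concDraws <- function(conc, nIter, rows = NULL) {
  if (is.matrix(conc) || is.data.frame(conc)) {
    X <- .asConcentrationTable(conc)
    if (is.null(rows)) {
      rows <- sample.int(nrow(X), nIter, replace = TRUE)
    }
    out <- X[rows, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "rows") <- rows
    out
  } else if (is.list(conc)) {
    stopifnot(!is.null(names(conc)))
    out <- sapply(conc, function(sp) {
      if (is(sp, "DistributionSpec")) drawSamples(sp, nIter)
      else rep(as.numeric(sp), nIter)
    })
    matrix(out, nIter, length(conc), dimnames = list(NULL, names(conc)))
  } else if (is.numeric(conc)) {
    stopifnot(!is.null(names(conc)))
    matrix(conc, nIter, length(conc), byrow = TRUE,
           dimnames = list(NULL, names(conc)))
  } else {
    stop("unsupported concentration input", call. = FALSE)
  }
}

.concConfig <- function(conc) {
  if (is.matrix(conc) || is.data.frame(conc)) {
    list(mode = "empirical", dim = dim(as.matrix(conc)),
         colMeans = colMeans(as.matrix(conc)))
  } else if (is.list(conc)) {
    list(mode = "specs", specs = lapply(conc, function(sp) {
      if (is(sp, "DistributionSpec")) specToList(sp) else as.numeric(sp)
    }))
  } else {
    list(mode = "point", values = conc)
  }
}

.factorsConfig <- function(factors) {
  list(
    population = factors@population,
    BW = specToList(factors@BW), ED = specToList(factors@ED),
    SA = specToList(factors@SA), AF = specToList(factors@AF),
    IRing = specToList(factors@IRing), EF = specToList(factors@EF),
    abfNc = factors@abfNoncarcinogenic,
    abfCarc = factors@abfCarcinogenic,
    afCarcinogenic = factors@afCarcinogenic, cf = factors@cf
  )
}

.newRiskResult <- function(population, mode, label, seed, draws,
                           components, fingerprint) {
  new("RiskResult",
      population = population, mode = mode, label = label,
      nIter = nrow(draws), seed = as.integer(seed), draws = draws,
      components = components, summary = .summaryFromDraws(draws),
      configFingerprint = fingerprint)
}

#' Concentration-oriented Monte Carlo health-risk assessment
#'
#' Runs the seeded Monte Carlo simulation of the whole-soil exposure
#' model for one population: each iteration draws one value per exposure
#' parameter and one concentration per element, computes every
#' element-pathway hazard quotient and cancer risk, and accumulates the
#' hazard index (HI) and total carcinogenic risk (TCR).
#'
#' Concentration input modes: a sample-by-element matrix (rows resampled
#' with replacement — empirical mode), a named list of
#' [DistributionSpec-class] per element (fitted-distribution mode), or a
#' named numeric vector (point mode, the mode used for replication runs
#' where only per-element mean concentrations are published).
#'
#' @param conc concentration input (see Details).
#' @param factors an [ExposureFactors-class].
#' @param tox toxicity table, see [toxicityTable()].
#' @param nIter iterations (default 10000, >= 100).
#' @param seed integer master seed; the run is bitwise reproducible.
#' @return a [RiskResult-class].
#' @examples
#' r <- runConcentrationHRA(studyConcentrations(),
#'                          exposureFactors("children"),
#'                          nIter = 1000, seed = 1)
#' riskSummary(r)$HI$mean
#' @export
runConcentrationHRA <- function(conc, factors, tox = toxicityTable(),
                                nIter = 10000L, seed = 1L) {
  stopifnot(is(factors, "ExposureFactors"), nIter >= 100)
  nIter <- as.integer(nIter)
  fp <- .configFingerprint(list(
    mode = "concentration", conc = .concConfig(conc),
    factors = .factorsConfig(factors), tox = tox, nIter = nIter
  ))
  res <- .withSeed(seed, {
    draw <- drawExposure(factors, nIter)
    concMat <- .concDraws(conc, nIter)
    .riskFromConc(concMat, draw, tox)
  })
  .newRiskResult(factors@population, "concentration", "total", seed,
                 data.frame(HI = res$HI, TCR = res$TCR),
                 list(HQ = res$HQ, CR = res$CR), fp)
}

#' Source-oriented Monte Carlo health-risk assessment
#'
#' As [runConcentrationHRA()], but per pollution source, with one shared
#' set of exposure-parameter draws across the sources of a run so that
#' per-source risks are comparable and summable. Source inputs are
#' either per-source named lists of per-element
#' [DistributionSpec-class] / point values (fitted-distribution mode,
#' e.g. [sourceProfileSpecs()]) or per-source concentration tables from
#' a mass-conserving decomposition ([sourceConcentrations()]); in the
#' table mode the same resampled row indices are shared across sources,
#' so summed per-source draws equal the whole-soil draws exactly.
#'
#' @param sources named list of per-source inputs (see Details).
#' @inheritParams runConcentrationHRA
#' @return named list of per-source [RiskResult-class] objects plus a
#'   `combined` result whose draws are the across-source sums.
#' @export
runSourceHRA <- function(sources, factors, tox = toxicityTable(),
                         nIter = 10000L, seed = 1L) {
  stopifnot(is(factors, "ExposureFactors"), nIter >= 100)
  if (!length(sources)) stop("source set is empty", call. = FALSE)
  nIter <- as.integer(nIter)
  if (is.null(names(sources))) {
    names(sources) <- paste0("source", seq_along(sources))
  }
  fp <- .configFingerprint(list(
    mode = "source",
    sources = lapply(sources, .concConfig),
    factors = .factorsConfig(factors), tox = tox, nIter = nIter
  ))
  res <- .withSeed(seed, {
    draw <- drawExposure(factors, nIter)
    tabular <- vapply(sources, function(s) is.matrix(s) || is.data.frame(s),
                      logical(1))
    rows <- if (any(tabular)) {
      sample.int(nrow(as.matrix(sources[[which(tabular)[1]]])), nIter,
                 replace = TRUE)
    } else NULL
    concs <- lapply(sources, function(s) {
      if (is.matrix(s) || is.data.frame(s)) .concDraws(s, nIter, rows = rows)
      else .concDraws(s, nIter)
    })
    lapply(concs, .riskFromConc, draw = draw, tox = tox)
  })
  out <- lapply(names(sources), function(nm) {
    r <- res[[nm]]
    .newRiskResult(factors@population, "source", nm, seed,
                   data.frame(HI = r$HI, TCR = r$TCR),
                   list(HQ = r$HQ, CR = r$CR), fp)
  })
  names(out) <- names(sources)
  combined <- data.frame(
    HI = Reduce(`+`, lapply(res, `[[`, "HI")),
    TCR = Reduce(`+`, lapply(res, `[[`, "TCR"))
  )
  out$combined <- .newRiskResult(factors@population, "source", "combined",
                                 seed, combined, list(), fp)
  out
}

#' @rdname summarizeRisk
#' @export
riskDraws <- function(result) result@draws

#' @rdname summarizeRisk
#' @export
riskSummary <- function(result) result@summary

#' Summarize a Monte Carlo risk result
#'
#' Recomputes the summary statistics from the stored draws: mean, sd,
#' nearest-rank percentiles (5, 25, 50, 75, 95; the value at sorted
#' position `ceiling(p/100 * n)`), and the exceedance probabilities
#' P(HI > 1), P(TCR > 1e-6), P(TCR > 1e-4).
#'
#' @param result a [RiskResult-class].
#' @return nested list with `HI` and `TCR` components.
#' @export
summarizeRisk <- function(result) {
  stopifnot(is(result, "RiskResult"))
  .summaryFromDraws(result@draws)
}

#' Percent share of combined mean carcinogenic risk per source
#'
#' `share_k = 100 * mean(CR_k) / sum_kk mean(CR_kk)` over the per-source
#' results of one [runSourceHRA()] run; shares sum to 100.
#'
#' @param results named list of per-source [RiskResult-class] objects
#'   (a `combined` entry, if present, is ignored).
#' @param metric `"TCR"` (default) or `"HI"`.
#' @return named numeric vector of percentages.
#' @export
sourceContributionShares <- function(results, metric = c("TCR", "HI")) {
  metric <- match.arg(metric)
  results <- results[setdiff(names(results), "combined")]
  means <- vapply(results, function(r) mean(r@draws[[metric]]), numeric(1))
  100 * means / sum(means)
}

#' Monte Carlo convergence report
#'
#' Running mean and standard error of the HI and TCR draws at the given
#' iteration checkpoints; the run is flagged stable when the relative
#' change of both running means over the last checkpoint interval is
#' below 1%.
#'
#' @param result a [RiskResult-class].
#' @param checkpoints increasing iteration counts (default 1000, 2000,
#'   5000 and the full run).
#' @return data.frame with columns `n`, `meanHI`, `seHI`, `meanTCR`,
#'   `seTCR`, and attribute `stable`.
#' @export
convergenceReport <- function(result,
                              checkpoints = c(1000L, 2000L, 5000L,
                                              result@nIter)) {
  checkpoints <- sort(unique(pmin(as.integer(checkpoints), result@nIter)))
  hi <- result@draws$HI; tcr <- result@draws$TCR
  tab <- do.call(rbind, lapply(checkpoints, function(n) {
    data.frame(n = n,
               meanHI = mean(hi[seq_len(n)]),
               seHI = sd(hi[seq_len(n)]) / sqrt(n),
               meanTCR = mean(tcr[seq_len(n)]),
               seTCR = sd(tcr[seq_len(n)]) / sqrt(n))
  }))
  stable <- FALSE
  if (nrow(tab) >= 2) {
    last <- nrow(tab)
    relHI <- abs(tab$meanHI[last] - tab$meanHI[last - 1]) /
      max(abs(tab$meanHI[last]), .Machine$double.eps)
    relTCR <- abs(tab$meanTCR[last] - tab$meanTCR[last - 1]) /
      max(abs(tab$meanTCR[last]), .Machine$double.eps)
    stable <- relHI < 0.01 && relTCR < 0.01
  }
  attr(tab, "stable") <- stable
  tab
}

#' Export a risk result to JSON (and optionally per-draw CSV)
#'
#' Writes the summary (with population, mode, iteration count, seed and
#' configuration fingerprint) as JSON; optionally the raw HI/TCR draws
#' as CSV alongside.
#'
#' @param result a [RiskResult-class].
#' @param path output JSON path.
#' @param drawsCsv optional path for the per-draw CSV.
#' @return `path`, invisibly.
#' @export
exportRiskResult <- function(result, path, drawsCsv = NULL) {
  s <- summarizeRisk(result)
  obj <- list(
    population = result@population, mode = result@mode,
    label = result@label, nIter = result@nIter, seed = result@seed,
    configFingerprint = result@configFingerprint,
    HI = list(mean = s$HI$mean, sd = s$HI$sd,
              percentiles = as.list(s$HI$percentiles),
              pExceed1 = s$HI$exceedance),
    TCR = list(mean = s$TCR$mean, sd = s$TCR$sd,
               percentiles = as.list(s$TCR$percentiles),
               pExceed1e6 = s$TCR$exceedance1e6,
               pExceed1e4 = s$TCR$exceedance1e4)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(drawsCsv)) {
    utils::write.csv(cbind(iteration = seq_len(result@nIter),
                           result@draws,
                           configFingerprint = result@configFingerprint),
                     drawsCsv, row.names = FALSE)
  }
  invisible(path)
}
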