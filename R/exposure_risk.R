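# Averaging-time constants of the USEPA dose model: noncarcinogenic
# AT = 365 * ED days (ED cancels from the dose), carcinogenic
# AT = 365 * 70 = 25550 days.
.AT_CARC <- 25550
.DAYS_PER_YEAR <- 365

.ELEMENTS <- c("Zn", "Cu", "Cr", "Pb", "Hg")

#' Population exposure-factor sets
#'
#' Returns the default exposure-parameter distributions for a population
#' group: body weight (lognormal, arithmetic mean/sd), exposure duration
#' (uniform), exposed skin area (normal from 50th/95th percentiles,
#' truncated below at 0), soil adherence factor (beta-PERT), soil
#' ingestion rate (lognormal from 50th/95th percentiles) and exposure
#' frequency (triangular), together with the point-valued dermal
#' absorption fractions and the conversion factor CF = 1e-6 kg/mg.
#'
#' Children: BW ~ lognormal(19.6, 1.96) kg, ED ~ U(0, 6) y,
#' SA 50th 2074 / 95th 2493 cm^2, AF PERT(0, 0.2, 3.3) mg/(cm^2 d),
#' IR 50th 100 / 95th 200 mg/d. Adults (female/male): BW ~
#' lognormal(57.59, 8.3) / lognormal(67.55, 8.72) kg, ED ~ U(0, 24) y,
#' SA 50th 5039 / 95th 5938 cm^2, AF PERT(0, 0.07, 0.3),
#' IR 50th 50 / 95th 200 mg/d. All groups share
#' EF ~ triangular(180, 350, 365) d/y and noncarcinogenic ABF 0.001.
#'
#' Two conventions are deliberately configurable because the published
#' dermal parameterization is internally ambiguous:
#' `abfCarcinogenic` defaults to 0.001 (the value consistent with
#' published carcinogenic-risk magnitudes; the tabulated literal 0.01 is
#' available by argument), and the carcinogenic pathway uses the
#' most-likely adherence value (`afCarcinogenic = "point"`) rather than
#' the full PERT by default, again matching published magnitudes. The
#' noncarcinogenic pathway always samples the full PERT. Results record
#' which convention was used via the configuration fingerprint.
#'
#' @param population `"children"`, `"female"` or `"male"`.
#' @param abfCarcinogenic dermal absorption fraction for the
#'   carcinogenic endpoint (default 0.001; tabulated literal 0.01).
#' @param afCarcinogenic `"point"` (default) or `"pert"`.
#' @return an [ExposureFactors-class].
#' @examples
#' exposureFactors("children")
#' @export
exposureFactors <- function(population = c("children", "female", "male"),
                            abfCarcinogenic = 0.001,
                            afCarcinogenic = c("point", "pert")) {
  population <- match.arg(population)
  afCarcinogenic <- match.arg(afCarcinogenic)
  adult <- population != "children"
  bw <- switch(population,
    children = distSpec("lognormal_mean_sd", mean = 19.6, sd = 1.96),
    female = distSpec("lognormal_mean_sd", mean = 57.59, sd = 8.3),
    male = distSpec("lognormal_mean_sd", mean = 67.55, sd = 8.72)
  )
  new("ExposureFactors",
    population = population,
    BW = bw,
    ED = distSpec("uniform", min = 0, max = if (adult) 24 else 6),
    SA = if (adult) {
      distSpec("normal_p50_p95", p50 = 5039, p95 = 5938, lower = 0)
    } else {
      distSpec("normal_p50_p95", p50 = 2074, p95 = 2493, lower = 0)
    },
    AF = if (adult) {
      distSpec("beta_pert", min = 0, mode = 0.07, max = 0.3)
    } else {
      distSpec("beta_pert", min = 0, mode = 0.2, max = 3.3)
    },
    IRing = if (adult) {
      distSpec("lognormal_p50_p95", p50 = 50, p95 = 200)
    } else {
      distSpec("lognormal_p50_p95", p50 = 100, p95 = 200)
    },
    EF = distSpec("triangular", min = 180, mode = 350, max = 365),
    abfNoncarcinogenic = 0.001,
    abfCarcinogenic = abfCarcinogenic,
    cf = 1e-6,
    afCarcinogenic = afCarcinogenic
  )
}

#' Toxicity reference values
#'
#' Default oral and dermal reference doses (RfD, mg/(kg d)) and cancer
#' slope factors (SF, (kg d)/mg) for the five soil metals. `NA` marks an
#' absent slope factor: Zn, Cu and Hg carry no carcinogenic slope, and
#' Pb has an oral slope only, so those pathways contribute zero cancer
#' risk by construction.
#'
#' @return data.frame with rownames `Zn, Cu, Cr, Pb, Hg` and columns
#'   `RfDing`, `RfDdermal`, `SFing`, `SFdermal`.
#' @export
toxicityTable <- function() {
  data.frame(
    RfDing    = c(0.3,   0.04,  3.0e-3,  3.50e-3, 3.0e-4),
    RfDdermal = c(0.06,  0.012, 6.0e-5,  5.25e-4, 2.1e-5),
    SFing     = c(NA,    NA,    0.5,     8.5e-3,  NA),
    SFdermal  = c(NA,    NA,    20,      NA,      NA),
    row.names = .ELEMENTS
  )
}

#' Draw exposure-parameter values for a population
#'
#' One draw per iteration per parameter, shared across all elements and
#' pathways of that iteration (parameters are population-level). ED
#' draws of exactly 0 are rejected and redrawn (the dose model divides
#' by the ED-proportional averaging time). Returns both adherence-factor
#' columns: `AF` (beta-PERT draw, used by the noncarcinogenic dermal
#' pathway) and `AFcarc` (the most-likely point value or the same PERT
#' draw, per the `afCarcinogenic` convention of `factors`).
#'
#' @param factors an [ExposureFactors-class].
#' @param n number of iterations.
#' @param seed optional integer seed (draws consume the current RNG
#'   stream when `NULL`).
#' @return data.frame with `n` rows and columns `BW`, `ED`, `SA`, `AF`,
#'   `AFcarc`, `IRing`, `EF`, `abfNc`, `abfCarc`, `cf`.
#' @export
drawExposure <- function(factors, n, seed = NULL) {
  stopifnot(is(factors, "ExposureFactors"))
  if (!is.null(seed)) return(.withSeed(seed, drawExposure(factors, n)))
  n <- as.integer(n)
  ed <- drawSamples(factors@ED, n)
  while (any(ed == 0)) {
    ed[ed == 0] <- drawSamples(factors@ED, sum(ed == 0))
  }
  af <- drawSamples(factors@AF, n)
  afc <- if (factors@afCarcinogenic == "point") {
    p <- factors@AF@params
    rep(if ("mode" %in% names(p)) p[["mode"]] else mean(factors@AF), n)
  } else {
    af
  }
  data.frame(
    BW = drawSamples(factors@BW, n),
    ED = ed,
    SA = drawSamples(factors@SA, n),
    AF = af,
    AFcarc = afc,
    IRing = drawSamples(factors@IRing, n),
    EF = drawSamples(factors@EF, n),
    abfNc = factors@abfNoncarcinogenic,
    abfCarc = factors@abfCarcinogenic,
    cf = factors@cf
  )
}

# point-valued draw (medians/modes/means are NOT used here: each spec's
# point value only exists for point families; used for deterministic
# oracles where the caller supplies explicit values)
.checkDraw <- function(draw, cols) {
  missing <- setdiff(cols, names(draw))
  if (length(missing)) {
    stop("draw is missing component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (cl in cols) {
    if (any(draw[[cl]] <= 0)) {
      stop(sprintf("draw component '%s' must be positive", cl),
           call. = FALSE)
    }
  }
}

#' Average daily dose via incidental soil ingestion
#'
#' `ADD_ing = C * IR * CF * EF * ED / (BW * AT)` with AT = 365 * ED days
#' for the noncarcinogenic endpoint — implemented in the algebraically
#' reduced form `C * IR * CF * EF / (BW * 365)` so ED cancels exactly
#' (and a zero ED can never produce 0/0) — and AT = 25550 days for the
#' carcinogenic endpoint, where ED stays explicit.
#'
#' Vectorized over iterations: `C` and every component of `draw` may be
#' scalars or vectors of the iteration length.
#'
#' @param C soil concentration, mg/kg (>= 0).
#' @param draw list or data.frame of sampled exposure values; needs
#'   `IRing`, `EF`, `BW`, `cf` (and `ED` for the carcinogenic endpoint).
#'   See [drawExposure()].
#' @param endpoint `"noncarcinogenic"` or `"carcinogenic"`.
#' @return dose in mg/(kg d), same length as the draws.
#' @examples
#' addIngestion(37.31, list(IRing = 100, EF = 350, BW = 19.6, cf = 1e-6),
#'              "noncarcinogenic")
#' @export
addIngestion <- function(C, draw,
                         endpoint = c("noncarcinogenic", "carcinogenic")) {
  endpoint <- match.arg(endpoint)
  if (any(C < 0)) stop("negative concentration", call. = FALSE)
  if (endpoint == "noncarcinogenic") {
    .checkDraw(draw, c("IRing", "EF", "BW", "cf"))
    C * draw$IRing * draw$cf * draw$EF / (draw$BW * .DAYS_PER_YEAR)
  } else {
    .checkDraw(draw, c("IRing", "EF", "BW", "cf", "ED"))
    C * draw$IRing * draw$cf * draw$EF * draw$ED / (draw$BW * .AT_CARC)
  }
}

#' Average daily dose via dermal contact
#'
#' `ADD_dermal = C * CF * SA * AF * ABF * EF * ED / (BW * AT)`, with the
#' same endpoint-dependent averaging-time treatment as [addIngestion()].
#' The absorption fraction and adherence factor are selected by
#' endpoint: the noncarcinogenic pathway uses `draw$AF` and
#' `draw$abfNc`, the carcinogenic pathway `draw$AFcarc` and
#' `draw$abfCarc`.
#'
#' @inheritParams addIngestion
#' @param draw needs `SA`, `EF`, `BW`, `cf`, plus `AF`/`abfNc`
#'   (noncarcinogenic) or `AFcarc`/`abfCarc`/`ED` (carcinogenic).
#' @return dose in mg/(kg d).
#' @export
addDermal <- function(C, draw,
                      endpoint = c("noncarcinogenic", "carcinogenic")) {
  endpoint <- match.arg(endpoint)
  if (any(C < 0)) stop("negative concentration", call. = FALSE)
  if (endpoint == "noncarcinogenic") {
    .checkDraw(draw, c("SA", "AF", "EF", "BW", "cf", "abfNc"))
    C * draw$cf * draw$SA * draw$AF * draw$abfNc * draw$EF /
      (draw$BW * .DAYS_PER_YEAR)
  } else {
    .checkDraw(draw, c("SA", "AFcarc", "EF", "BW", "cf", "abfCarc", "ED"))
    C * draw$cf * draw$SA * draw$AFcarc * draw$abfCarc * draw$EF *
      draw$ED / (draw$BW * .AT_CARC)
  }
}

#' Hazard quotients for one element
#'
#' `HQ = ADD / RfD` per pathway. Errors if the element has no reference
#' dose in the toxicity table.
#'
#' @param element element name (row of `tox`).
#' @param ADDing,ADDdermal noncarcinogenic doses, mg/(kg d) (vectors
#'   allowed).
#' @param tox toxicity table, see [toxicityTable()].
#' @return list with components `ing` and `dermal`.
#' @export
hazardQuotient <- function(element, ADDing, ADDdermal,
                           tox = toxicityTable()) {
  if (!element %in% rownames(tox)) {
    stop(sprintf("element '%s' missing from toxicity table", element),
         call. = FALSE)
  }
  row <- tox[element, ]
  if (is.na(row$RfDing) || is.na(row$RfDdermal)) {
    stop(sprintf("missing RfD for element '%s'", element), call. = FALSE)
  }
  list(ing = ADDing / row$RfDing, dermal = ADDdermal / row$RfDdermal)
}

#' Hazard index and its risk band
#'
#' HI is the sum of hazard quotients over elements and pathways.
#' Classification bands (closed on the left): `HI < 1` acceptable,
#' `1 <= HI < 4` moderate, `HI >= 4` high.
#'
#' @param hqs numeric vector (or list, flattened) of hazard quotients;
#'   empty input gives HI = 0.
#' @return list with `HI` and `classification`.
#' @export
hazardIndex <- function(hqs) {
  hi <- sum(unlist(hqs))
  if (!length(hqs)) hi <- 0
  cls <- if (hi < 1) "acceptable" else if (hi < 4) "moderate" else "high"
  list(HI = hi, classification = cls)
}

#' Carcinogenic risk for one element
#'
#' `CR = ADD * SF` per pathway; a pathway with no slope factor
#' contributes exactly zero (e.g. the dermal pathway of Pb, and both
#' pathways of Zn, Cu, Hg).
#'
#' @param element element name.
#' @param ADDing,ADDdermal carcinogenic doses, mg/(kg d).
#' @param tox toxicity table.
#' @return list with components `ing` and `dermal`.
#' @export
cancerRisk <- function(element, ADDing, ADDdermal, tox = toxicityTable()) {
  if (!element %in% rownames(tox)) {
    stop(sprintf("element '%s' missing from toxicity table", element),
         call. = FALSE)
  }
  row <- tox[element, ]
  list(
    ing = if (is.na(row$SFing)) ADDing * 0 else ADDing * row$SFing,
    dermal = if (is.na(row$SFdermal)) ADDdermal * 0
             else ADDdermal * row$SFdermal
  )
}

#' Total carcinogenic risk and its risk band
#'
#' TCR is the sum of per-element, per-pathway cancer risks.
#' Classification: `< 1e-6` acceptable, `[1e-6, 1e-4]` tolerable,
#' `> 1e-4` unacceptable.
#'
#' @param crs numeric vector (or list, flattened) of cancer risks; empty
#'   input gives TCR = 0.
#' @return list with `TCR` and `classification`.
#' @export
totalCancerRisk <- function(crs) {
  tcr <- sum(unlist(crs))
  if (!length(crs)) tcr <- 0
  cls <- if (tcr < 1e-6) "acceptable" else if (tcr <= 1e-4) "tolerable"
         else "unacceptable"
  list(TCR = tcr, classification = cls)
}

# vectorized core: HI and TCR draws from an iterations-by-elements
# concentration matrix and a shared exposure-draw data.frame
.riskFromConc <- function(concMat, draw, tox) {
  elements <- colnames(concMat)
  nIter <- nrow(concMat)
  HQ <- CR <- matrix(0, nIter, length(elements),
                     dimnames = list(NULL, elements))
  for (el in elements) {
    C <- concMat[, el]
    dIngN <- addIngestion(C, draw, "noncarcinogenic")
    dDerN <- addDermal(C, draw, "noncarcinogenic")
    hq <- hazardQuotient(el, dIngN, dDerN, tox)
    HQ[, el] <- hq$ing + hq$dermal
    row <- tox[el, ]
    if (!is.na(row$SFing) || !is.na(row$SFdermal)) {
      dIngC <- addIngestion(C, draw, "carcinogenic")
      dDerC <- addDermal(C, draw, "carcinogenic")
      cr <- cancerRisk(el, dIngC, dDerC, tox)
      CR[, el] <- cr$ing + cr$dermal
    }
  }
  list(HI = rowSums(HQ), TCR = rowSums(CR), HQ = HQ, CR = CR)
}

#' Source-resolved risk under shared exposure draws
#'
#' Applies the dose and risk equations to each source's concentrations
#' with one shared set of exposure-parameter draws, so that per-source
#' risks are directly comparable and — when the sources come from a
#' mass-conserving decomposition of a measured table — sum exactly to
#' the whole-soil risk draw by draw.
#'
#' @param sources named list; each entry is an iterations-by-elements
#'   concentration draw matrix (or a single-row matrix / named vector of
#'   point concentrations, recycled across iterations).
#' @param draw exposure draws from [drawExposure()] (its row count sets
#'   the iteration count).
#' @param tox toxicity table.
#' @return named list per source, each with `HI`, `TCR`, `HQ`, `CR`
#'   draw components (as in the Monte Carlo engine), plus a `combined`
#'   entry with the summed draws.
#' @export
sourceRisk <- function(sources, draw, tox = toxicityTable()) {
  if (!length(sources)) stop("source set is empty", call. = FALSE)
  if (is.null(names(sources))) {
    names(sources) <- paste0("source", seq_along(sources))
  }
  nIter <- length(draw$BW)
  out <- lapply(sources, function(s) {
    if (is.null(dim(s))) s <- matrix(s, 1, dimnames = list(NULL, names(s)))
    if (nrow(s) == 1 && nIter > 1) {
      s <- matrix(s, nIter, ncol(s), byrow = TRUE,
                  dimnames = list(NULL, colnames(s)))
    }
    .riskFromConc(s, draw, tox)
  })
  combined <- list(
    HI = Reduce(`+`, lapply(out, `[[`, "HI")),
    TCR = Reduce(`+`, lapply(out, `[[`, "TCR"))
  )
  c(out, list(combined = combined))
}
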