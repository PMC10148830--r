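#' @importFrom stats runif rnorm rlnorm rbeta rt qlogis dnorm dlnorm dlogis
#'   dt plogis pnorm plnorm pt sd mad median optim ks.test quantile var
NULL

# run `expr` under a fixed seed without disturbing the caller's RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# deterministic sub-seed derivation: documented splitting rule so that
# every population / source run has an independent stream below 2^31
.deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(offset)) %%
               2147483629)
}

#' Construct a validated distribution specification
#'
#' Builds a [DistributionSpec-class] in one of the supported
#' parameterizations and checks the family's invariants (support
#' ordering, positivity, truncation ordering). Location-scale families
#' (`student_t_loc_scale`, `logistic`, `gumbel_max`) with `scale = 0`
#' degrade to a point mass at their location, mirroring tabulated fits
#' whose scale rounds to zero.
#'
#' @param family one of `"point"`, `"uniform"`, `"triangular"`,
#'   `"normal_p50_p95"`, `"lognormal_mean_sd"`, `"lognormal_p50_p95"`,
#'   `"beta_pert"`, `"student_t_loc_scale"`, `"logistic"`,
#'   `"gumbel_max"`.
#' @param ... named numeric parameters for the family:
#'   \describe{
#'     \item{point}{`value`}
#'     \item{uniform}{`min`, `max`}
#'     \item{triangular / beta_pert}{`min`, `mode`, `max` (beta-PERT also
#'       accepts `lambda`, default 4)}
#'     \item{normal_p50_p95 / lognormal_p50_p95}{`p50`, `p95`}
#'     \item{lognormal_mean_sd}{arithmetic `mean`, `sd`}
#'     \item{student_t_loc_scale}{`midpoint`, `scale` (and `df`,
#'       default 5)}
#'     \item{logistic}{`mean`, `scale`}
#'     \item{gumbel_max}{`likeliest`, `scale`}
#'   }
#' @param lower,upper optional truncation bounds; sampling is by
#'   rejection within `[lower, upper]`.
#' @return a `DistributionSpec`.
#' @examples
#' distSpec("uniform", min = 0, max = 6)                 # exposure duration
#' distSpec("triangular", min = 180, mode = 350, max = 365)
#' distSpec("beta_pert", min = 0, mode = 0.2, max = 3.3)
#' @export
distSpec <- function(family, ..., lower = -Inf, upper = Inf) {
  if (length(family) != 1L || !family %in% .DIST_FAMILIES) {
    stop(sprintf("unknown family '%s'; supported: %s",
                 paste(family, collapse = ","),
                 paste(.DIST_FAMILIES, collapse = ", ")), call. = FALSE)
  }
  params <- c(...)
  if (length(params) && is.null(names(params))) {
    stop("parameters must be named", call. = FALSE)
  }
  opt <- .DIST_OPTIONAL[[family]]
  if (!is.null(opt)) {
    add <- setdiff(names(opt), names(params))
    params <- c(params, opt[add])
  }
  # degrade rule: unbounded-support location-scale family, zero scale
  if (family %in% c("student_t_loc_scale", "logistic", "gumbel_max") &&
      !is.na(params["scale"]) && params[["scale"]] == 0) {
    loc <- switch(family,
      student_t_loc_scale = params[["midpoint"]],
      logistic = params[["mean"]],
      gumbel_max = params[["likeliest"]]
    )
    family <- "point"
    params <- c(value = loc)
  }
  if (is.na(lower) || is.null(lower)) lower <- -Inf
  if (is.na(upper) || is.null(upper)) upper <- Inf
  new("DistributionSpec", family = family, params = params,
      lowerTrunc = as.numeric(lower), upperTrunc = as.numeric(upper))
}

#' @rdname distSpec
#' @param spec a `DistributionSpec`.
#' @return `specFamily` returns the family tag; `specParams` the named
#'   parameter vector; `isTruncated` a logical.
#' @export
specFamily <- function(spec) spec@family

#' @rdname distSpec
#' @export
specParams <- function(spec) spec@params

#' @rdname distSpec
#' @export
isTruncated <- function(spec) {
  is.finite(spec@lowerTrunc) || is.finite(spec@upperTrunc)
}

# lognormal_mean_sd: arithmetic (mean, sd) -> (meanlog, sdlog)
.lnormPars <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Analytic mean of a distribution specification
#'
#' Closed-form expected values per family: uniform `(min+max)/2`;
#' triangular `(min+mode+max)/3`; beta-PERT
#' `(min + lambda*mode + max)/(lambda+2)`; Gumbel-max
#' `likeliest + gamma*scale` (Euler-Mascheroni gamma); logistic and
#' location-scale Student-t, their location (Student-t requires
#' `df > 1`); `lognormal_p50_p95` `p50*exp(sigma^2/2)` with
#' `sigma = log(p95/p50)/1.6449`; `normal_p50_p95`, `p50`. For a
#' truncated spec the mean has no closed form here and is approximated
#' by 1e5 rejection draws under a fixed internal seed; the result then
#' carries the attribute `approximate = TRUE`.
#'
#' @param x a [DistributionSpec-class].
#' @param ... ignored.
#' @return numeric(1), the expected value.
#' @export
setMethod("mean", "DistributionSpec", function(x, ...) {
  if (isTruncated(x)) {
    v <- mean(drawSamples(x, 1e5L, seed = 990001L))
    attr(v, "approximate") <- TRUE
    return(v)
  }
  p <- x@params
  switch(x@family,
    point = p[["value"]],
    uniform = (p[["min"]] + p[["max"]]) / 2,
    triangular = (p[["min"]] + p[["mode"]] + p[["max"]]) / 3,
    normal_p50_p95 = p[["p50"]],
    lognormal_mean_sd = p[["mean"]],
    lognormal_p50_p95 = {
      sigma <- log(p[["p95"]] / p[["p50"]]) / .Z95
      p[["p50"]] * exp(sigma^2 / 2)
    },
    beta_pert = (p[["min"]] + p[["lambda"]] * p[["mode"]] + p[["max"]]) /
      (p[["lambda"]] + 2),
    student_t_loc_scale = {
      if (p[["df"]] <= 1) stop("mean undefined for Student-t with df <= 1",
                               call. = FALSE)
      p[["midpoint"]]
    },
    logistic = p[["mean"]],
    gumbel_max = p[["likeliest"]] + .EULER_GAMMA * p[["scale"]]
  )
})

# core sampler on the current RNG stream, no truncation
.sampleCore <- function(spec, n) {
  p <- spec@params
  switch(spec@family,
    point = rep(p[["value"]], n),
    uniform = runif(n, p[["min"]], p[["max"]]),
    triangular = {
      # inverse CDF
      u <- runif(n)
      a <- p[["min"]]; m <- p[["mode"]]; b <- p[["max"]]
      fc <- (m - a) / (b - a)
      ifelse(u < fc,
             a + sqrt(u * (b - a) * (m - a)),
             b - sqrt((1 - u) * (b - a) * (b - m)))
    },
    normal_p50_p95 = rnorm(n, p[["p50"]], (p[["p95"]] - p[["p50"]]) / .Z95),
    lognormal_mean_sd = {
      lp <- .lnormPars(p[["mean"]], p[["sd"]])
      rlnorm(n, lp[["meanlog"]], lp[["sdlog"]])
    },
    lognormal_p50_p95 = rlnorm(n, log(p[["p50"]]),
                               log(p[["p95"]] / p[["p50"]]) / .Z95),
    beta_pert = {
      a <- p[["min"]]; m <- p[["mode"]]; b <- p[["max"]]
      lam <- p[["lambda"]]
      al <- 1 + lam * (m - a) / (b - a)
      be <- 1 + lam * (b - m) / (b - a)
      a + (b - a) * rbeta(n, al, be)
    },
    student_t_loc_scale = p[["midpoint"]] + p[["scale"]] * rt(n, p[["df"]]),
    logistic = qlogis(runif(n), p[["mean"]], p[["scale"]]),
    gumbel_max = p[["likeliest"]] - p[["scale"]] * log(-log(runif(n)))
  )
}

#' Draw reproducible samples from a distribution specification
#'
#' Samples use the inverse-CDF transform where a closed form exists
#' (uniform, triangular, logistic, Gumbel-max) and standard stock
#' transforms otherwise. Truncation is enforced by rejection resampling
#' (never clipping), so the distribution within the bounds is the exact
#' conditional distribution; if the acceptance rate falls below 1e-4 the
#' call errors rather than hanging.
#'
#' @param spec a [DistributionSpec-class].
#' @param n number of draws (>= 1).
#' @param seed optional integer; when given, draws are bitwise
#'   reproducible and the caller's RNG state is untouched. When `NULL`
#'   the current RNG stream is consumed (the mode used inside the Monte
#'   Carlo engine).
#' @return numeric vector of length `n`, all values within the
#'   truncation bounds.
#' @examples
#' drawSamples(distSpec("point", value = 0.001), 5)
#' x <- drawSamples(distSpec("uniform", min = 0, max = 6), 1000, seed = 1)
#' @export
drawSamples <- function(spec, n, seed = NULL) {
  stopifnot(is(spec, "DistributionSpec"), n >= 1)
  n <- as.integer(n)
  if (!is.null(seed)) return(.withSeed(seed, drawSamples(spec, n)))
  if (!isTruncated(spec)) return(.sampleCore(spec, n))
  lo <- spec@lowerTrunc; hi <- spec@upperTrunc
  if (spec@family == "point") {
    v <- spec@params[["value"]]
    if (v < lo || v > hi) {
      stop("truncation bounds exclude the point mass", call. = FALSE)
    }
    return(rep(v, n))
  }
  out <- numeric(0)
  proposed <- 0
  while (length(out) < n) {
    batch <- max(n - length(out), 1000L)
    # inflate the batch once the acceptance rate is known to be low
    if (proposed > 0) {
      rate <- max(length(out) / proposed, 1e-3)
      batch <- ceiling((n - length(out)) / rate)
    }
    batch <- min(batch, 1e7L)
    x <- .sampleCore(spec, batch)
    proposed <- proposed + batch
    out <- c(out, x[x >= lo & x <= hi])
    if (proposed >= 1e4 && length(out) / proposed < 1e-4) {
      stop("truncation bounds exclude essentially all probability mass ",
           sprintf("(acceptance rate %.2g)", length(out) / proposed),
           call. = FALSE)
    }
  }
  out[seq_len(n)]
}

## ---- densities / CDFs for fitting and goodness of fit ----------------

.dgumbelmax <- function(x, loc, scale, log = FALSE) {
  z <- (x - loc) / scale
  ld <- -log(scale) - z - exp(-z)
  if (log) ld else exp(ld)
}
.pgumbelmax <- function(q, loc, scale) exp(-exp(-(q - loc) / scale))

.dstls <- function(x, loc, scale, df, log = FALSE) {
  ld <- dt((x - loc) / scale, df, log = TRUE) - log(scale)
  if (log) ld else exp(ld)
}
.pstls <- function(q, loc, scale, df) pt((q - loc) / scale, df)

.dtri <- function(x, a, m, b) {
  d <- numeric(length(x))
  left <- x >= a & x <= m
  right <- x > m & x <= b
  if (m > a) d[left] <- 2 * (x[left] - a) / ((b - a) * (m - a))
  d[right] <- 2 * (b - x[right]) / ((b - a) * (b - m))
  d
}
.ptri <- function(q, a, m, b) {
  p <- numeric(length(q))
  p[q >= b] <- 1
  left <- q > a & q <= m
  right <- q > m & q < b
  p[left] <- (q[left] - a)^2 / ((b - a) * (m - a))
  p[right] <- 1 - (b - q[right])^2 / ((b - a) * (b - m))
  p
}

# families supported by fitSpec, in the tie-breaking enum order
.FIT_FAMILIES <- c("normal", "lognormal", "logistic", "gumbel_max",
                   "student_t_loc_scale", "uniform", "triangular")

#' Fit a distribution family to data
#'
#' Estimates parameters in the tabulated parameterizations. Normal,
#' lognormal and logistic fits are maximum likelihood via
#' \pkg{fitdistrplus}; Gumbel-max and fixed-df location-scale Student-t
#' are maximum likelihood by direct optimization (moment-based starting
#' values); uniform uses the MLE `(min(x), max(x))`; triangular uses a
#' documented method-of-moments fallback (`min`/`max` at the data range,
#' `mode = 3*mean - min - max` clamped to the range), since its MLE is
#' notoriously unstable. Constant data degrade to a point spec for every
#' family.
#'
#' @param data numeric vector, length >= 8.
#' @param family one of `"normal"`, `"lognormal"`, `"logistic"`,
#'   `"gumbel_max"`, `"student_t_loc_scale"`, `"uniform"`,
#'   `"triangular"`.
#' @param df degrees of freedom held fixed for the Student-t fit.
#' @return a [DistributionSpec-class] (families `normal_p50_p95`,
#'   `lognormal_mean_sd`, `logistic`, `gumbel_max`,
#'   `student_t_loc_scale`, `uniform`, `triangular`), with attributes
#'   `logLik` and `npar`.
#' @export
fitSpec <- function(data, family, df = 5) {
  family <- match.arg(family, .FIT_FAMILIES)
  data <- as.numeric(data)
  if (length(data) < 8) stop("need at least 8 observations", call. = FALSE)
  if (anyNA(data)) stop("data contain NA", call. = FALSE)
  if (diff(range(data)) == 0) {
    sp <- distSpec("point", value = data[1])
    attr(sp, "logLik") <- Inf
    attr(sp, "npar") <- 1L
    return(sp)
  }
  n <- length(data)
  out <- switch(family,
    normal = {
      f <- fitdistrplus::fitdist(data, "norm")
      est <- f$estimate
      sp <- distSpec("normal_p50_p95", p50 = est[["mean"]],
                     p95 = est[["mean"]] + .Z95 * est[["sd"]])
      list(sp = sp, ll = f$loglik, np = 2L)
    },
    lognormal = {
      if (any(data <= 0)) {
        stop("lognormal fit requires strictly positive data", call. = FALSE)
      }
      f <- fitdistrplus::fitdist(data, "lnorm")
      mu <- f$estimate[["meanlog"]]; s <- f$estimate[["sdlog"]]
      m <- exp(mu + s^2 / 2)
      sp <- distSpec("lognormal_mean_sd", mean = m,
                     sd = m * sqrt(exp(s^2) - 1))
      list(sp = sp, ll = f$loglik, np = 2L)
    },
    logistic = {
      f <- fitdistrplus::fitdist(data, "logis")
      sp <- distSpec("logistic", mean = f$estimate[["location"]],
                     scale = f$estimate[["scale"]])
      list(sp = sp, ll = f$loglik, np = 2L)
    },
    gumbel_max = {
      s0 <- sd(data) * sqrt(6) / pi
      l0 <- mean(data) - .EULER_GAMMA * s0
      nll <- function(par) {
        if (par[2] <= 0) return(1e10)
        -sum(.dgumbelmax(data, par[1], par[2], log = TRUE))
      }
      o <- optim(c(l0, s0), nll)
      sp <- distSpec("gumbel_max", likeliest = o$par[1], scale = o$par[2])
      list(sp = sp, ll = -o$value, np = 2L)
    },
    student_t_loc_scale = {
      s0 <- max(mad(data), sd(data) / 2)
      nll <- function(par) {
        if (par[2] <= 0) return(1e10)
        -sum(.dstls(data, par[1], par[2], df, log = TRUE))
      }
      o <- optim(c(median(data), s0), nll)
      sp <- distSpec("student_t_loc_scale", midpoint = o$par[1],
                     scale = o$par[2], df = df)
      list(sp = sp, ll = -o$value, np = 2L)
    },
    uniform = {
      a <- min(data); b <- max(data)
      sp <- distSpec("uniform", min = a, max = b)
      list(sp = sp, ll = -n * log(b - a), np = 2L)
    },
    triangular = {
      a <- min(data); b <- max(data)
      m <- min(max(3 * mean(data) - a - b, a), b)
      sp <- distSpec("triangular", min = a, mode = m, max = b)
      ll <- sum(log(pmax(.dtri(data, a, m, b), 1e-300)))
      list(sp = sp, ll = ll, np = 3L)
    }
  )
  sp <- out$sp
  attr(sp, "logLik") <- out$ll
  attr(sp, "npar") <- out$np
  sp
}

# CDF of a fitted (untruncated) spec, for the K-S statistic
.specCDF <- function(spec) {
  p <- spec@params
  switch(spec@family,
    point = function(q) as.numeric(q >= p[["value"]]),
    uniform = function(q) punif(q, p[["min"]], p[["max"]]),
    triangular = function(q) .ptri(q, p[["min"]], p[["mode"]], p[["max"]]),
    normal_p50_p95 = function(q)
      pnorm(q, p[["p50"]], (p[["p95"]] - p[["p50"]]) / .Z95),
    lognormal_mean_sd = function(q) {
      lp <- .lnormPars(p[["mean"]], p[["sd"]])
      plnorm(q, lp[["meanlog"]], lp[["sdlog"]])
    },
    lognormal_p50_p95 = function(q)
      plnorm(q, log(p[["p50"]]), log(p[["p95"]] / p[["p50"]]) / .Z95),
    beta_pert = function(q) {
      a <- p[["min"]]; m <- p[["mode"]]; b <- p[["max"]]; lam <- p[["lambda"]]
      pbeta((q - a) / (b - a), 1 + lam * (m - a) / (b - a),
            1 + lam * (b - m) / (b - a))
    },
    student_t_loc_scale = function(q)
      .pstls(q, p[["midpoint"]], p[["scale"]], p[["df"]]),
    logistic = function(q) plogis(q, p[["mean"]], p[["scale"]]),
    gumbel_max = function(q) .pgumbelmax(q, p[["likeliest"]], p[["scale"]])
  )
}

#' Select the best-fitting family by AIC
#'
#' Fits each candidate family by [fitSpec()] and returns the one with
#' the smallest AIC; ties are broken by the smaller Kolmogorov-Smirnov
#' statistic, then by the candidate enum order (`normal`, `lognormal`,
#' `logistic`, `gumbel_max`, `student_t_loc_scale`, `uniform`,
#' `triangular`). This reproduces the batch-fit workflow commonly used
#' to tabulate per-source concentration distributions.
#'
#' @param data numeric vector (length >= 8).
#' @param candidates character vector of >= 2 families (see
#'   [fitSpec()]); a single candidate is allowed and returned as-is.
#' @param df Student-t degrees of freedom (fixed).
#' @return list with `best` (a `DistributionSpec`) and `ranking` (a
#'   data.frame with columns `family`, `aic`, `ks`, ordered as ranked).
#' @export
selectBestFit <- function(data, candidates, df = 5) {
  candidates <- match.arg(candidates, .FIT_FAMILIES, several.ok = TRUE)
  fits <- list(); aic <- ks <- numeric(0); fams <- character(0)
  errors <- character(0)
  for (fam in candidates) {
    res <- tryCatch(fitSpec(data, fam, df = df), error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("%s: %s", fam, conditionMessage(res)))
      next
    }
    fams <- c(fams, fam)
    fits[[fam]] <- res
    aic <- c(aic, 2 * attr(res, "npar") - 2 * attr(res, "logLik"))
    cdf <- .specCDF(res)
    kstat <- suppressWarnings(ks.test(data, cdf)$statistic)
    ks <- c(ks, unname(kstat))
  }
  if (!length(fams)) {
    stop("all candidate fits failed:\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  }
  ord <- order(aic, ks, match(fams, .FIT_FAMILIES))
  ranking <- data.frame(family = fams[ord], aic = aic[ord], ks = ks[ord],
                        row.names = NULL)
  list(best = fits[[fams[ord[1]]]], ranking = ranking)
}

## ---- config serialization --------------------------------------------

#' Serialize / deserialize distribution specs
#'
#' A spec round-trips through the plain-list configuration form
#' `list(family = , params = , truncation = list(lower = , upper = ))`,
#' the shape stored in YAML/JSON run configurations. Infinite bounds are
#' omitted on write and restored on read.
#'
#' @param spec a [DistributionSpec-class].
#' @return `specToList` a plain list; `specFromList` a
#'   `DistributionSpec`.
#' @export
specToList <- function(spec) {
  out <- list(family = spec@family, params = as.list(spec@params))
  tr <- list()
  if (is.finite(spec@lowerTrunc)) tr$lower <- spec@lowerTrunc
  if (is.finite(spec@upperTrunc)) tr$upper <- spec@upperTrunc
  if (length(tr)) out$truncation <- tr
  out
}

#' @rdname specToList
#' @param x a list as produced by `specToList`.
#' @export
specFromList <- function(x) {
  stopifnot(is.list(x), !is.null(x$family), !is.null(x$params))
  tr <- x$truncation
  do.call(distSpec, c(list(family = x$family), x$params,
                      list(lower = if (is.null(tr$lower)) -Inf else tr$lower,
                           upper = if (is.null(tr$upper)) Inf else tr$upper)))
}
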