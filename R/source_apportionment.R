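#' @importFrom stats punif pbeta
NULL

# validate a concentration table: numeric matrix, no NA, non-negative,
# element colnames
.asConcentrationTable <- function(table) {
  if (is.data.frame(table)) table <- as.matrix(table)
  if (!is.matrix(table) || !is.numeric(table)) {
    stop("concentration table must be a numeric matrix or data frame",
         call. = FALSE)
  }
  if (anyNA(table)) stop("concentration table has missing values",
                         call. = FALSE)
  if (any(table < 0)) stop("concentration table has negative entries",
                           call. = FALSE)
  if (is.null(colnames(table))) {
    colnames(table) <- paste0("E", seq_len(ncol(table)))
  }
  table
}

# one multiplicative-update NMF run on the (scaled) matrix
.nmfRun <- function(X, k, maxIter, tol) {
  n <- nrow(X); m <- ncol(X)
  eps <- 1e-12
  scl <- sqrt(mean(X) / k)
  G <- matrix(runif(n * k, 0.2, 1), n, k) * scl
  P <- matrix(runif(k * m, 0.2, 1), k, m) * scl
  errPrev <- Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    P <- P * (crossprod(G, X) / (crossprod(G) %*% P + eps))
    GP <- G %*% P
    G <- G * (tcrossprod(X, P) / (G %*% tcrossprod(P) + eps))
    if (it %% 20 == 0 || it == maxIter) {
      err <- sqrt(sum((X - G %*% P)^2))
      if (is.finite(errPrev) && errPrev - err <= tol * max(errPrev, eps)) {
        converged <- TRUE
        break
      }
      errPrev <- err
    }
  }
  list(G = G, P = P, err = sqrt(sum((X - G %*% P)^2)),
       converged = converged)
}

#' Factorize a concentration table into non-negative sources
#'
#' Decomposes the sample-by-element table `X` into `k` non-negative
#' latent sources, `X ~ G %*% P`, the receptor-model view of the data as
#' a linear combination of unknown source compositions. The surrogate
#' algorithm is multiplicative-update non-negative matrix factorization
#' run on the column-mean-scaled table (each element divided by its mean
#' so that trace elements such as Hg carry weight comparable to major
#' elements), with `nRestarts` random initializations and the
#' best-objective run kept. The scale indeterminacy is fixed by
#' normalizing each composition row of `P` to sum to 1 and absorbing the
#' scale into `G`; sources are ordered by decreasing total contribution.
#'
#' Diagnostics: `perElementR2` is the centered coefficient of
#' determination per element; `estimatedSN` is the ratio of the k-th to
#' the (k+1)-th singular value of the column-standardized table, a
#' signal-to-noise surrogate for the number of recoverable source
#' dimensions (it is not identical to EPA Unmix's NUMFACT statistic).
#' The conventional acceptance rule for a trustworthy model is min
#' R-squared >= `minR2` and S/N >= `minSN`; violations raise a warning,
#' never an error.
#'
#' @param table numeric sample-by-element matrix (mg/kg), non-negative,
#'   no missing values.
#' @param k number of sources, `1 <= k < min(n, m)`.
#' @param seed integer seed controlling the restarts (deterministic).
#' @param nRestarts random initializations (best kept).
#' @param maxIter,tol multiplicative-update iteration cap and relative
#'   convergence tolerance on the Frobenius error.
#' @param dropOutliers if `TRUE`, samples with any element beyond its
#'   mean +/- 3 sd are removed before factorization (a conventional
#'   receptor-model screening step; off by default).
#' @param minR2,minSN acceptance-rule thresholds (warnings only).
#' @return a [SourceModel-class].
#' @examples
#' g <- matrix(rexp(40), 40, 1); p <- matrix(c(5, 1, 0.2), 1, 3)
#' fit <- factorizeSources(g %*% p, k = 1, seed = 1)
#' perElementR2(fit)  # all 1: exact rank-1 input
#' @export
factorizeSources <- function(table, k, seed = 1L, nRestarts = 10L,
                             maxIter = 5000L, tol = 1e-9,
                             dropOutliers = FALSE,
                             minR2 = 0.8, minSN = 2) {
  X <- .asConcentrationTable(table)
  if (dropOutliers) {
    mu <- colMeans(X); s <- apply(X, 2, sd)
    keep <- rowSums(sweep(abs(sweep(X, 2, mu)), 2, 3 * s, ">")) == 0
    X <- X[keep, , drop = FALSE]
  }
  n <- nrow(X); m <- ncol(X)
  if (k < 1 || k >= min(n, m)) {
    stop(sprintf("k must satisfy 1 <= k < min(n, m) = %d", min(n, m)),
         call. = FALSE)
  }
  colMu <- colMeans(X)
  if (any(colMu == 0)) {
    stop("an element column is identically zero", call. = FALSE)
  }
  Xs <- sweep(X, 2, colMu, "/")
  best <- NULL
  .withSeed(seed, {
    for (r in seq_len(nRestarts)) {
      run <- .nmfRun(Xs, k, maxIter, tol)
      if (is.null(best) || run$err < best$err) best <- run
    }
  })
  G <- best$G
  P <- sweep(best$P, 2, colMu, "*")  # back to concentration scale
  # fix scale: composition rows sum to 1, scale absorbed into G
  rs <- rowSums(P)
  rs[rs == 0] <- 1
  P <- sweep(P, 1, rs, "/")
  G <- sweep(G, 2, rs, "*")
  # deterministic source order: decreasing total contribution
  ord <- order(colSums(G), decreasing = TRUE)
  G <- G[, ord, drop = FALSE]
  P <- P[ord, , drop = FALSE]
  pred <- G %*% P
  sstot <- colSums(sweep(X, 2, colMeans(X))^2)
  ssres <- colSums((X - pred)^2)
  r2 <- 1 - ssres / sstot
  names(r2) <- colnames(X)
  # S/N surrogate: singular-value ratio of the column-standardized table
  Z <- scale(X)
  sv <- svd(Z, nu = 0, nv = 0)$d
  sn <- if (k + 1 <= length(sv) && sv[k + 1] > 0) sv[k] / sv[k + 1] else Inf
  if (min(r2) < minR2 || sn < minSN) {
    warning(sprintf(
      "model-acceptance rule not met: min R2 = %.3f (>= %.2f), S/N = %.2f (>= %.2f)",
      min(r2), minR2, sn, minSN), call. = FALSE)
  }
  dimnames(G) <- list(rownames(X), paste0("source", seq_len(k)))
  dimnames(P) <- list(paste0("source", seq_len(k)), colnames(X))
  new("SourceModel", G = G, P = P, perElementR2 = r2,
      estimatedSN = as.numeric(sn), nSources = as.integer(k),
      seed = as.integer(seed), converged = best$converged)
}

#' @rdname factorizeSources
#' @param model a [SourceModel-class].
#' @return `contributions` the sample-by-source matrix `G`;
#'   `compositions` the source-by-element matrix `P`; `predicted` the
#'   reconstruction `G %*% P`; `perElementR2` and `estimatedSN` the
#'   diagnostics.
#' @export
contributions <- function(model) model@G

#' @rdname factorizeSources
#' @export
compositions <- function(model) model@P

#' @rdname factorizeSources
#' @export
predicted <- function(model) model@G %*% model@P

#' @rdname factorizeSources
#' @export
perElementR2 <- function(model) model@perElementR2

#' @rdname factorizeSources
#' @export
estimatedSN <- function(model) model@estimatedSN

#' Per-sample per-element source fractions from a fitted model
#'
#' For each sample `i` and element `j`, the fraction of the modeled
#' concentration attributed to source `k` is
#' `F[i, j, k] = G[i, k] * P[k, j] / sum_kk(G[i, kk] * P[kk, j])`. Where
#' the modeled concentration is exactly zero the fraction is undefined
#' and defaults to the uniform `1/k` (with a warning noting how many
#' cells were affected). The population-level element share is
#' `100 * sum_i(G[i, k] * P[k, j]) / sum_i sum_kk(G[i, kk] * P[kk, j])`,
#' the percent of each element's total mass carried by each source.
#'
#' @param model a [SourceModel-class].
#' @return a [ContributionFractions-class].
#' @export
contributionFractions <- function(model) {
  G <- model@G; P <- model@P
  n <- nrow(G); k <- ncol(G); m <- ncol(P)
  f <- array(0, dim = c(n, m, k),
             dimnames = list(rownames(G), colnames(P), rownames(P)))
  for (kk in seq_len(k)) f[, , kk] <- outer(G[, kk], P[kk, ])
  denom <- apply(f, c(1, 2), sum)
  zero <- denom == 0
  if (any(zero)) {
    warning(sprintf(
      "%d sample-element cell(s) have zero modeled concentration; uniform 1/k fractions used",
      sum(zero)), call. = FALSE)
  }
  for (kk in seq_len(k)) {
    fk <- f[, , kk]
    fk[!zero] <- fk[!zero] / denom[!zero]
    fk[zero] <- 1 / k
    f[, , kk] <- fk
  }
  mass <- sapply(seq_len(k), function(kk) colSums(outer(G[, kk], P[kk, ])))
  # mass: m x k matrix of per-element per-source modeled totals
  share <- t(sweep(mass, 1, rowSums(mass), "/")) * 100
  dimnames(share) <- list(rownames(P), colnames(P))
  new("ContributionFractions", fractions = f, elementShare = share)
}

#' @rdname contributionFractions
#' @param fractions a [ContributionFractions-class].
#' @return `fractionTensor` the samples x elements x sources array;
#'   `elementShare` the sources x elements percent matrix.
#' @export
fractionTensor <- function(fractions) fractions@fractions

#' @rdname contributionFractions
#' @export
elementShare <- function(fractions) fractions@elementShare

#' Source-resolved concentration tables
#'
#' Applies the fraction tensor to the measured table:
#' `C_k[i, j] = F[i, j, k] * X[i, j]`, so the per-source tables sum
#' exactly back to the measured table (mass conservation).
#'
#' @param fractions a [ContributionFractions-class].
#' @param table the measured sample-by-element concentration matrix the
#'   fractions refer to.
#' @return named list of `k` concentration matrices, one per source.
#' @export
sourceConcentrations <- function(fractions, table) {
  X <- .asConcentrationTable(table)
  f <- fractions@fractions
  d <- dim(f)
  if (d[1] != nrow(X) || d[2] != ncol(X)) {
    stop("dimension mismatch between fractions and table", call. = FALSE)
  }
  out <- lapply(seq_len(d[3]), function(kk) f[, , kk] * X)
  names(out) <- dimnames(f)[[3]]
  out
}

#' Constant-loading source fractions from published percentages
#'
#' Builds a [ContributionFractions-class] directly from a published
#' source-by-element percentage loading matrix, applied uniformly to
#' every sample — the alternative reading of the hybrid model in which
#' each element's source split is the population-level loading rather
#' than sample-specific. Each element's percentages must sum to at most
#' 100; any remainder is assigned to an explicit `"unattributed"` source
#' so that mass conservation still holds.
#'
#' @param table sample-by-element concentration matrix (defines the
#'   sample dimension and element names).
#' @param percentages k x m non-negative matrix of percent loadings,
#'   columns = elements of `table`.
#' @return a [ContributionFractions-class] (with an extra
#'   `"unattributed"` source when any column sums below 100).
#' @examples
#' x <- matrix(80, 3, 1, dimnames = list(NULL, "Pb"))
#' f <- externalCompositionModel(x, matrix(c(55, 16, 16, 13), 4, 1))
#' @export
externalCompositionModel <- function(table, percentages) {
  X <- .asConcentrationTable(table)
  W <- as.matrix(percentages)
  if (ncol(W) != ncol(X)) {
    stop("percentage matrix must have one column per element",
         call. = FALSE)
  }
  if (any(W < 0)) stop("negative percentages", call. = FALSE)
  cs <- colSums(W)
  if (any(cs > 100 + 1e-9)) {
    stop(sprintf("column sum exceeds 100%% for element(s): %s",
                 paste(colnames(X)[cs > 100 + 1e-9], collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(rownames(W))) rownames(W) <- paste0("source", seq_len(nrow(W)))
  if (any(cs < 100 - 1e-9)) {
    W <- rbind(W, unattributed = 100 - cs)
  }
  n <- nrow(X); m <- ncol(X); k <- nrow(W)
  f <- array(0, dim = c(n, m, k),
             dimnames = list(rownames(X), colnames(X), rownames(W)))
  for (kk in seq_len(k)) {
    f[, , kk] <- matrix(W[kk, ] / 100, n, m, byrow = TRUE)
  }
  colnames(W) <- colnames(X)
  new("ContributionFractions", fractions = f, elementShare = W)
}
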