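# shared helpers for the suite: all fixtures are built in code

cosineSim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# best cosine match between recovered and true composition rows over
# source permutations (k small)
bestRowMatchCosines <- function(recovered, truth) {
  k <- nrow(truth)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- rep(-Inf, k)
  for (p in perms(seq_len(k))) {
    cs <- vapply(seq_len(k),
                 function(i) cosineSim(recovered[p[i], ], truth[i, ]),
                 numeric(1))
    if (min(cs) > min(best)) best <- cs
  }
  best
}

# exposure-factor set in which every parameter is a point mass, for
# deterministic Monte Carlo checks
pointExposureFactors <- function(BW = 19.6, ED = 3, SA = 2074, AF = 0.2,
                                 IR = 100, EF = 350, population = "children") {
  new("ExposureFactors",
      population = population,
      BW = distSpec("point", value = BW),
      ED = distSpec("point", value = ED),
      SA = distSpec("point", value = SA),
      AF = distSpec("point", value = AF),
      IRing = distSpec("point", value = IR),
      EF = distSpec("point", value = EF),
      abfNoncarcinogenic = 0.001, abfCarcinogenic = 0.001,
      cf = 1e-6, afCarcinogenic = "point")
}

# a small random source model built through the public factorization
randomSourceModel <- function(seed = 1, n = 40, m = 4, k = 2) {
  set.seed(seed)
  G <- matrix(rexp(n * k, rate = 1), n, k)
  P <- matrix(runif(k * m, 0.1, 1), k, m)
  P <- sweep(P, 1, rowSums(P), "/")
  X <- (G %*% P) * (1 + 0.03 * matrix(rnorm(n * m), n, m))
  X[X < 0] <- 0
  colnames(X) <- paste0("E", seq_len(m))
  suppressWarnings(factorizeSources(X, k = k, seed = seed, nRestarts = 5))
}
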