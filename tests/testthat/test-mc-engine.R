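studyConc <- studyConcentrations()

test_that("all-point parameters collapse the simulation to a constant", {
  pf <- pointExposureFactors()
  r <- runConcentrationHRA(studyConc, pf, nIter = 200, seed = 1)
  d <- riskDraws(r)
  expect_identical(sd(d$HI), 0)
  expect_identical(sd(d$TCR), 0)
  # the Monte Carlo mean equals the deterministic computation
  draw <- as.list(drawExposure(pf, 1, seed = 1))
  det <- sourceRisk(list(all = studyConc), draw)
  expect_equal(mean(d$HI), det$all$HI, tolerance = 1e-12)
  expect_equal(mean(d$TCR), det$all$TCR, tolerance = 1e-12)
  s <- riskSummary(r)
  expect_equal(unname(s$HI$percentiles), rep(mean(d$HI), 5))
})

test_that("runs are bitwise reproducible for a fixed seed", {
  f <- exposureFactors("children")
  a <- runConcentrationHRA(studyConc, f, nIter = 500, seed = 99)
  b <- runConcentrationHRA(studyConc, f, nIter = 500, seed = 99)
  expect_identical(riskDraws(a), riskDraws(b))
  expect_identical(a@configFingerprint, b@configFingerprint)
  # a different configuration yields a different fingerprint
  c2 <- runConcentrationHRA(studyConc, exposureFactors("male"),
                            nIter = 500, seed = 99)
  expect_false(identical(a@configFingerprint, c2@configFingerprint))
})

test_that("doubling concentrations doubles risk under shared seed", {
  f <- exposureFactors("children")
  a <- runConcentrationHRA(studyConc, f, nIter = 2000, seed = 21)
  b <- runConcentrationHRA(2 * studyConc, f, nIter = 2000, seed = 21)
  expect_equal(riskDraws(b)$HI, 2 * riskDraws(a)$HI, tolerance = 1e-12)
  expect_equal(riskDraws(b)$TCR, 2 * riskDraws(a)$TCR, tolerance = 1e-12)
})

test_that("all three concentration input modes run and agree in mean", {
  f <- exposureFactors("children")
  sv <- emulateStudy(seed = 2)
  emp <- runConcentrationHRA(sv$table, f, nIter = 3000, seed = 4)
  pt <- runConcentrationHRA(colMeans(sv$table), f, nIter = 3000, seed = 4)
  specs <- lapply(colnames(sv$table), function(el) {
    distSpec("lognormal_mean_sd", mean = mean(sv$table[, el]),
             sd = sd(sv$table[, el]))
  })
  names(specs) <- colnames(sv$table)
  sm <- runConcentrationHRA(specs, f, nIter = 3000, seed = 4)
  m <- vapply(list(emp, pt, sm), function(r) riskSummary(r)$HI$mean,
              numeric(1))
  expect_lt(max(m) / min(m), 1.15)  # same expected concentrations
  expect_error(runConcentrationHRA(studyConc, f, nIter = 10), "nIter")
})

test_that("source mode with one source matches concentration mode", {
  f <- exposureFactors("children")
  whole <- runConcentrationHRA(studyConc, f, nIter = 1000, seed = 31)
  src <- runSourceHRA(list(all = studyConc), f, nIter = 1000, seed = 31)
  expect_identical(riskDraws(whole)$HI, riskDraws(src$all)$HI)
  expect_identical(riskDraws(whole)$TCR, riskDraws(src$all)$TCR)
})

test_that("mass-conserving source tables sum to whole-soil draws", {
  sv <- emulateStudy(seed = 6)
  f <- exposureFactors("children")
  fit <- suppressWarnings(factorizeSources(sv$table, 4, seed = 1,
                                           nRestarts = 5))
  tabs <- sourceConcentrations(contributionFractions(fit), sv$table)
  src <- runSourceHRA(tabs, f, nIter = 1000, seed = 8)
  whole <- runConcentrationHRA(sv$table, f, nIter = 1000, seed = 8)
  sumHI <- Reduce(`+`, lapply(src[names(tabs)],
                              function(r) riskDraws(r)$HI))
  sumTCR <- Reduce(`+`, lapply(src[names(tabs)],
                               function(r) riskDraws(r)$TCR))
  expect_equal(sumHI, riskDraws(whole)$HI, tolerance = 1e-9)
  expect_equal(sumTCR, riskDraws(whole)$TCR, tolerance = 1e-9)
  expect_equal(riskDraws(src$combined)$HI, sumHI, tolerance = 1e-12)
})

test_that("risk responds monotonically to RfD and SF", {
  f <- exposureFactors("children")
  tox <- toxicityTable()
  toxUp <- tox; toxUp$RfDing <- tox$RfDing * 2; toxUp$RfDdermal <- tox$RfDdermal * 2
  a <- runConcentrationHRA(studyConc, f, tox, nIter = 500, seed = 13)
  b <- runConcentrationHRA(studyConc, f, toxUp, nIter = 500, seed = 13)
  expect_true(all(riskDraws(b)$HI < riskDraws(a)$HI))
  toxSF <- tox; toxSF["Cr", "SFing"] <- 1
  c3 <- runConcentrationHRA(studyConc, f, toxSF, nIter = 500, seed = 13)
  expect_true(all(riskDraws(c3)$TCR > riskDraws(a)$TCR))
})

test_that("summaries use nearest-rank percentiles and exact exceedance", {
  r <- runConcentrationHRA(studyConc, exposureFactors("children"),
                           nIter = 101, seed = 55)
  s <- summarizeRisk(r)
  hi <- sort(riskDraws(r)$HI)
  expect_identical(unname(s$HI$percentiles[["p5"]]),
                   hi[ceiling(0.05 * 101)])
  expect_identical(unname(s$HI$percentiles[["p50"]]),
                   hi[ceiling(0.50 * 101)])
  expect_identical(s$HI$exceedance, mean(riskDraws(r)$HI > 1))
  expect_lte(s$TCR$exceedance1e4, s$TCR$exceedance1e6)
  # summary stored in the object is recomputable from the draws
  expect_identical(riskSummary(r), s)
})

test_that("exceedance of synthetic uniform draws matches the binomial", {
  # P(U(0,2) > 1) = 0.5 within 3 binomial SEs at n = 1e5
  u <- drawSamples(distSpec("uniform", min = 0, max = 2), 1e5, seed = 77)
  r <- new("RiskResult", population = "children", mode = "concentration",
           label = "total", nIter = 1e5L, seed = 77L,
           draws = data.frame(HI = u, TCR = 0), components = list(),
           summary = list(), configFingerprint = "x")
  p <- summarizeRisk(r)$HI$exceedance
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 1e5))
})

test_that("source contribution shares sum to 100 and rank correctly", {
  f <- exposureFactors("children")
  src <- runSourceHRA(list(a = studyConc, b = studyConc), f,
                      nIter = 500, seed = 3)
  sh <- sourceContributionShares(src)
  expect_equal(unname(sum(sh)), 100, tolerance = 1e-6)
  expect_equal(unname(sh[["a"]]), 50, tolerance = 1e-9)  # equal sources
  # shares are invariant to a global concentration rescaling
  src2 <- runSourceHRA(list(a = 3 * studyConc, b = 3 * studyConc), f,
                       nIter = 500, seed = 3)
  expect_equal(sourceContributionShares(src2), sh, tolerance = 1e-9)
})

test_that("standard errors shrink like 1/sqrt(n)", {
  ratios <- vapply(1:5, function(seed) {
    r <- runConcentrationHRA(studyConc, exposureFactors("children"),
                             nIter = 8000, seed = 100 + seed)
    tab <- convergenceReport(r, checkpoints = c(2000, 8000))
    tab$seHI[2] / tab$seHI[1]
  }, numeric(1))
  expect_true(all(ratios > 0.4 & ratios < 0.6))
  # point-parameter runs have zero SE at every checkpoint
  rp <- runConcentrationHRA(studyConc, pointExposureFactors(),
                            nIter = 2000, seed = 1)
  tabp <- convergenceReport(rp, checkpoints = c(500, 1000, 2000))
  expect_identical(unique(tabp$seHI), 0)
  expect_true(attr(tabp, "stable"))
})

test_that("default-length runs are flagged stable at 10000 iterations", {
  r <- runConcentrationHRA(studyConc, exposureFactors("children"),
                           nIter = 10000, seed = 5)
  tab <- convergenceReport(r)
  expect_true(attr(tab, "stable"))
})

test_that("results export to JSON with the configuration fingerprint", {
  r <- runConcentrationHRA(studyConc, exposureFactors("children"),
                           nIter = 200, seed = 2)
  js <- tempfile(fileext = ".json"); cs <- tempfile(fileext = ".csv")
  exportRiskResult(r, js, drawsCsv = cs)
  obj <- jsonlite::read_json(js)
  expect_identical(obj$configFingerprint, r@configFingerprint)
  expect_equal(obj$HI$mean, riskSummary(r)$HI$mean, tolerance = 1e-12)
  dd <- read.csv(cs)
  expect_identical(nrow(dd), 200L)
})
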