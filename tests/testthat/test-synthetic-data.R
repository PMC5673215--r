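test_that("rate models validate their inputs", {
  expect_s4_class(rateModel(5), "RateModel")
  expect_error(rateModel(5, rates = c(1, 1)), "one entry per position")
  expect_error(rateModel(5, rates = c(-1, 1, 1, 1, 1)), "non-negative")
  expect_error(rateModel(5, neighborPenalty = 0), "neighborPenalty")
})

test_that("the absorbing state and frozen positions behave", {
  # equal rates, long time: everything ends fully deacetylated
  m <- rateModel(5, rates = rep(1e-2, 5))
  sim <- simulateDeacetylation(5, m, times = 1e5, nMolecules = 200,
                               seed = 4)
  expect_equal(names(sim$patternFreq[[1]]), "DDDDD")
  expect_equal(sim$acetatePerMolecule, 5)
  # a zero-rate reducing end never deacetylates
  m0 <- rateModel(5, rates = c(1e-2, 1e-2, 1e-2, 1e-2, 0))
  sim0 <- simulateDeacetylation(5, m0, times = c(10, 1e5),
                                nMolecules = 200, seed = 4)
  pats <- unlist(lapply(sim0$patternFreq, names))
  expect_true(all(substr(pats, 5, 5) == "A"))
})

test_that("empirical occupancy matches the closed form within 3 MC s.e.", {
  k <- c(0, 1, 1, 1, 0.2) * 1e-3
  m <- rateModel(5, rates = k)
  t <- 693
  p <- analyticOccupancy(5, m, t)$p
  expect_equal(unname(round(p, 2)), c(0, 0.5, 0.5, 0.5, 0.13))
  n <- 10000L
  sim <- simulateDeacetylation(5, m, times = t, nMolecules = n, seed = 9)
  freq <- sim$patternFreq[[1]]
  phat <- vapply(1:5, function(i)
    sum(freq[substr(names(freq), i, i) == "D"]), numeric(1))
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(phat - p) <= pmax(3 * se, 1e-12)))
  # expected acetate equals the sum of positional occupancies
  expect_equal(sim$acetatePerMolecule,
               sum(phat), tolerance = 1e-9)
  expect_equal(analyticOccupancy(5, m, 0)$expectedAcetate, 0)
  expect_error(analyticOccupancy(
    5, rateModel(5, neighborPenalty = 0.5), 10), "independent")
})

test_that("the neighbor penalty slows second deacetylations", {
  k <- rep(5e-3, 5)
  t <- 400
  nm <- 4000L
  free <- simulateDeacetylation(5, rateModel(5, rates = k), t, nm, seed = 2)
  pen <- simulateDeacetylation(
    5, rateModel(5, rates = k, neighborPenalty = 0.05), t, nm, seed = 2)
  expect_lt(pen$acetatePerMolecule, free$acetatePerMolecule)
  nDofPat <- function(freqs)
    sum(freqs * nchar(gsub("A", "", names(freqs))))
  # acetate bookkeeping is exact in both regimes
  expect_equal(nDofPat(free$patternFreq[[1]]), free$acetatePerMolecule,
               tolerance = 1e-9)
  expect_equal(nDofPat(pen$patternFreq[[1]]), pen$acetatePerMolecule,
               tolerance = 1e-9)
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- simulateDeacetylation(4, rateModel(4), c(100, 1000), 50, seed = 77)
  b <- simulateDeacetylation(4, rateModel(4), c(100, 1000), 50, seed = 77)
  expect_identical(a, b)
  s1 <- synthSpectrum(c(AADAA = 1), noise = spectrumNoise(
    mzJitterSd = 0.2, nNoisePeaks = 10, seed = 13))
  s2 <- synthSpectrum(c(AADAA = 1), noise = spectrumNoise(
    mzJitterSd = 0.2, nNoisePeaks = 10, seed = 13))
  expect_identical(peaks(s1), peaks(s2))
  c1 <- synthProteinCollection(seed = 3)
  c2 <- synthProteinCollection(seed = 3)
  expect_identical(c1, c2)
  # the generator does not perturb the caller's RNG stream
  set.seed(1); before <- .Random.seed
  invisible(synthProteinCollection(seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("synthetic spectra reject mixed-DP mixtures and survive jitter", {
  expect_error(synthSpectrum(c(AADAA = 1, AAD = 1)), "polymerization")
  # m/z jitter at 0.2 Da under a 0.5 tolerance: pattern recovery for
  # DP 5 mono-deacetylated species succeeds in at least 95 of 100 seeds
  pats <- c("DAAAA", "ADAAA", "AADAA", "AAADA", "AAAAD")
  hits <- 0L
  for (seed in 1:100) {
    truth <- pats[(seed - 1L) %% 5L + 1L]
    sp <- synthSpectrum(stats::setNames(1, truth),
                        noise = spectrumNoise(mzJitterSd = 0.2,
                                              nNoisePeaks = 5,
                                              seed = seed))
    rk <- rankPatterns(sp, 4, 1, checkPrecursor = FALSE)
    hits <- hits + (rk$pattern[1L] == truth)
  }
  expect_gte(hits, 95L)
})

test_that("protein generator plants exactly what it claims", {
  coll <- synthProteinCollection(seed = 8)
  expect_equal(length(coll$proteins), 64L)
  tr <- coll$truth
  # scanner hits equal planted positions for every motif-complete record
  for (i in which(tr$category %in% c("incomplete", "noSignalPeptide",
                                     "multiDomain", "positive"))) {
    s <- sub("\\*.*$", "", coll$proteins[[tr$id[i]]])
    hits <- scanMotifs(s)$hits
    got <- paste(hits$motifId, hits$start, sep = "@", collapse = ";")
    expect_identical(got, tr$motifStarts[i])
  }
  # zero positives: final funnel count is zero
  none <- synthProteinCollection(
    counts = c(nonCE4 = 2L, noMotifs = 2L, incomplete = 2L,
               noSignalPeptide = 2L, multiDomain = 2L, positive = 0L),
    seed = 8)
  f <- funnel(runCascade(none$proteins, none$truth[, c("id", "family")]))
  expect_equal(f$surviving[nrow(f)], 0L)
  expect_error(synthProteinCollection(counts = c(bad = 1L)), "categories")
})

test_that("simulate -> spectrum -> annotate recovers positional ordering", {
  # internal positions fastest, non-reducing end slower, reducing end
  # slowest: after annotating the mono-deacetylated pool the inferred
  # per-position support must reproduce that ordering
  model <- rateModel(5)
  sim <- simulateDeacetylation(5, model, times = 150, nMolecules = 10000,
                               seed = 31)
  freq <- sim$patternFreq[[1]]
  mono <- freq[nchar(gsub("A", "", names(freq))) == 1L]
  sp <- synthSpectrum(mono / sum(mono),
                      noise = spectrumNoise(mzJitterSd = 0.05,
                                            nNoisePeaks = 5, seed = 31))
  ps <- positionalSupport(rankPatterns(sp, 4, 1))
  internal <- mean(ps$f[c("pos2", "pos3", "pos4")])
  expect_gt(internal, ps$f[["pos1"]])       # internal > non-reducing end
  expect_gt(ps$f[["pos1"]], ps$f[["pos5"]]) # non-reducing > reducing end
})
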