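test_that("fragment ladders carry the label on Y ions only", {
  lad <- fragmentLadder(chosPattern("AADAA", "AMAC"))
  y <- lad[lad$ionType == "Y", ]
  b <- lad[lad$ionType == "B", ]
  expect_equal(nrow(y), 5L)
  expect_equal(nrow(b), 4L)
  expect_equal(y$mz[y$k == 1], 416.18, tolerance = 1e-2)
  # full-length Y is the intact precursor ion
  expect_equal(y$mz[y$k == 5], ionMz(chosPattern("AADAA", "AMAC")),
               tolerance = 1e-9)
  # B1 is the HexNAc oxocarbenium
  expect_equal(b$mz[b$k == 1], 204.09, tolerance = 1e-2)
  expect_error(fragmentLadder(chosPattern("AADAA"), ionTypes = "Y"),
               "label")
})

test_that("peak matching pairs ions with the nearest in-tolerance peak", {
  ions <- fragmentLadder(chosPattern("A", "AMAC"), ionTypes = "Y")
  sp <- newSpectrum(c(416.2), c(10), precursorMz = 416.2)
  expect_equal(nrow(matchPeaks(sp, ions, tol = 0.5)), 1L)
  sp2 <- newSpectrum(c(417.0), c(10), precursorMz = 417)
  expect_equal(nrow(matchPeaks(sp2, ions, tol = 0.5)), 0L)
  sp3 <- newSpectrum(c(416.0, 416.3), c(5, 7), precursorMz = 416.2)
  m <- matchPeaks(sp3, ions, tol = 0.5)
  expect_equal(m$peakMz, 416.3)  # nearest, not first
})

test_that("ranking recovers every pattern of DP <= 6 from its own ladder", {
  # exhaustive-enumeration oracle: the noiseless full Y+B ladder of a
  # pattern must rank that pattern first with explained fraction 1
  for (dp in 2:6) {
    for (pat in allPatternsOracle(dp)) {
      sp <- synthSpectrum(stats::setNames(1, pat),
                          noise = spectrumNoise(seed = 1))
      nD <- nchar(gsub("A", "", pat))
      rk <- rankPatterns(sp, nA = dp - nD, nD = nD)
      expect_equal(rk$pattern[1L], pat)
      expect_equal(rk$explainedFraction[1L], 1.0, tolerance = 1e-9)
      # the differential-ladder oracle agrees with the ranking winner
      yOnly <- synthSpectrum(stats::setNames(1, pat), bIntensity = 0,
                             noise = spectrumNoise(seed = 1))
      expect_equal(ladderReadPattern(peaks(yOnly)$mz), rk$pattern[1L])
    }
  }
})

test_that("a lone GlcNAc-AMAC peak leaves reducing-end-A patterns tied", {
  sp <- newSpectrum(416.18, 100, precursorMz = 1186.49)
  rk <- rankPatterns(sp, nA = 4, nD = 1)
  top <- rk$pattern[rk$score == max(rk$score)]
  expect_setequal(top, c("DAAAA", "ADAAA", "AADAA", "AAADA"))
  expect_equal(rk$pattern[5L], "AAAAD")
  expect_equal(rk$score[5L], 0)
})

test_that("empty spectra score zero everywhere and flag ambiguity", {
  sp <- newSpectrum(numeric(), numeric(), precursorMz = 1186.49)
  rk <- rankPatterns(sp, nA = 4, nD = 1)
  expect_true(all(rk$score == 0))
  ps <- positionalSupport(rk)
  expect_true(ps$ambiguity)
  expect_equal(unname(ps$f), rep(1 / 5, 5))  # uniform, sums to nD = 1
})

test_that("precursor/composition mismatch is rejected", {
  sp <- newSpectrum(416.18, 100, precursorMz = 1144.6)  # A3D2 precursor
  expect_error(rankPatterns(sp, nA = 4, nD = 1), "inconsistent")
})

test_that("positional support is an indicator for a single pattern and
           splits across an equal-abundance isomer pair", {
  sp <- synthSpectrum(c(AADAA = 1), noise = spectrumNoise(seed = 1))
  rk <- rankPatterns(sp, 4, 1)
  solo <- positionalSupport(rk[1L, , drop = FALSE])
  expect_equal(unname(solo$f), c(0, 0, 1, 0, 0))
  expect_false(solo$ambiguity)
  # merged equal-abundance AADAA + ADAAA: support shared by pos 2 and 3
  mix <- synthSpectrum(c(AADAA = 0.5, ADAAA = 0.5),
                       noise = spectrumNoise(seed = 1))
  rkm <- rankPatterns(mix, 4, 1)
  psm <- positionalSupport(rkm)
  expect_equal(psm$f[["pos2"]], psm$f[["pos3"]], tolerance = 1e-9)
  expect_gt(psm$f[["pos2"]] + psm$f[["pos3"]], 0.7)
  expect_lt(max(psm$f[["pos1"]], psm$f[["pos5"]]), 0.15)
  expect_true(psm$ambiguity)  # the two isomers are unresolvable
})

test_that("support frequencies always sum to nD under normalized weights", {
  for (seed in 1:5) {
    set.seed(seed)
    mixNames <- sample(c("AADAA", "ADAAA", "AAADA", "DAAAA", "AAAAD"), 3)
    mix <- stats::setNames(stats::runif(3, 0.1, 1), mixNames)
    sp <- synthSpectrum(mix, noise = spectrumNoise(mzJitterSd = 0.05,
                                                   nNoisePeaks = 3,
                                                   seed = seed))
    ps <- positionalSupport(rankPatterns(sp, 4, 1))
    expect_equal(sum(ps$f), 1, tolerance = 0.01)
  }
})

test_that("scores ignore peak order and intensity scale", {
  sp <- synthSpectrum(c(AADAA = 0.7, ADAAA = 0.3),
                      noise = spectrumNoise(seed = 2))
  pk <- peaks(sp)
  shuffled <- newSpectrum(rev(pk$mz), rev(pk$intensity) * 37.5,
                          precursorMz = precursorMz(sp))
  expect_equal(rankPatterns(sp, 4, 1)$score,
               rankPatterns(shuffled, 4, 1)$score, tolerance = 1e-12)
})

test_that("ends unsupported by the ladder get near-zero support", {
  # mono-deacetylated DP5 pool lacking both the GlcN-AMAC Y1 (374.17)
  # and the A4 Y4 ion: neither terminus can carry the deacetylation
  mix <- c(ADAAA = 1 / 3, AADAA = 1 / 3, AAADA = 1 / 3)
  sp <- synthSpectrum(mix, noise = spectrumNoise(seed = 1))
  yD <- ionMz(chosPattern("D", "AMAC"))
  yA4 <- fragmentLadder(chosPattern("DAAAA", "AMAC"),
                        ionTypes = "Y")$mz[4L]
  expect_false(any(abs(peaks(sp)$mz - yD) < 0.5))
  expect_false(any(abs(peaks(sp)$mz - yA4) < 0.5))
  ps <- positionalSupport(rankPatterns(sp, 4, 1))
  expect_lt(ps$f[["pos1"]], 0.1)
  expect_lt(ps$f[["pos5"]], 0.1)
  expect_lt(ps$f[["pos1"]], min(ps$f[c("pos2", "pos3", "pos4")]) / 3)
})

test_that("end diagnostics read the termini the way the spectra do", {
  # dominant 416 with weak 374: reducing end predominantly acetylated
  sp <- newSpectrum(c(374.17, 416.18), c(5, 100), precursorMz = 1186.49)
  d <- endDiagnostics(sp, 4, 1)
  expect_equal(d$reducingEnd, "predominantly acetylated")
  # no A4 Y4 ion in a (4,1) pool: non-reducing end not deacetylated
  expect_false(d$nonReducingEndDeacetylated)
  # only 374 at Y1: reducing end deacetylated
  sp2 <- newSpectrum(374.17, 50, precursorMz = 1186.49)
  expect_equal(endDiagnostics(sp2, 4, 1)$reducingEnd,
               "predominantly deacetylated")
  # A4-AMAC Y4 present: the non-reducing end D was lost on fragmentation
  yA4 <- fragmentLadder(chosPattern("AAAAA", "AMAC"),
                        ionTypes = "Y")$mz[4L]
  sp3 <- newSpectrum(c(416.18, yA4), c(100, 20), precursorMz = 1186.49)
  expect_true(endDiagnostics(sp3, 4, 1)$nonReducingEndDeacetylated)
})
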