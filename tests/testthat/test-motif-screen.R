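test_that("motif compilation follows the restricted syntax", {
  expect_equal(compileMotif("T[FY]DD")("AAATFDDKAA")$start, 4L)
  expect_equal(nrow(compileMotif("H[ST]xxH")("HSAAH")), 1L)
  expect_equal(nrow(compileMotif("DxxD[WY]")("DAADF")), 0L)  # F not in {W,Y}
  # overlapping occurrences are all reported
  expect_equal(compileMotif("LxH")("LLHH")$start, c(1L, 2L))
  expect_error(compileMotif("T[FY"), "offset")
  expect_error(compileMotif("T1DD"), "offset")
  expect_error(compileMotif("AB"), "length")
})

test_that("scanner agrees with a brute-force matcher on random sequences", {
  motifs <- ce4Motifs()
  set.seed(101)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  for (i in 1:1000) {
    s <- paste0(sample(aa, sample(20:500, 1L), replace = TRUE),
                collapse = "")
    hits <- scanMotifs(s, motifs, ordered = FALSE)$hits
    for (k in seq_len(nrow(motifs))) {
      got <- hits$start[hits$motifId == motifs$motifId[k]]
      expect_identical(as.integer(got),
                       as.integer(bruteMotifHits(motifs$pattern[k], s)))
    }
  }
})

test_that("all-present requires every motif, in order when configured", {
  sp <- function(n) strrep("G", n)
  good <- paste0("M", sp(10), "TFDD", sp(8), "HSAAH", sp(8), "RPPY",
                 sp(8), "DAADW", sp(8), "LAH", sp(10))
  expect_true(scanMotifs(good)$allPresent)
  expect_equal(scanMotifs(good)$chain$motifId, paste0("MT", 1:5))
  # deleting MT2 flips the call
  expect_false(scanMotifs(sub("HSAAH", sp(5), good))$allPresent)
  # MT5 before MT1: fails ordered mode, passes unordered
  swapped <- paste0("M", sp(10), "LAH", sp(8), "TFDD", sp(8), "HSAAH",
                    sp(8), "RPPY", sp(8), "DAADW", sp(10))
  expect_false(scanMotifs(swapped, ordered = TRUE)$allPresent)
  expect_true(scanMotifs(swapped, ordered = FALSE)$allPresent)
})

test_that("removing any single planted motif flips the screen verdict", {
  coll <- synthProteinCollection(seed = 11)
  pos <- coll$truth$id[coll$truth$category == "positive"]
  s <- coll$proteins[[pos]]
  expect_true(scanMotifs(s)$allPresent)
  for (inst in c("TFDD", "HSTAH", "RPPY", "DAADW", "LAH")) {
    mutated <- sub(inst, strrep("G", nchar(inst)), s)
    expect_false(scanMotifs(mutated)$allPresent)
  }
})

test_that("signal-peptide heuristic fires on planted positives only", {
  coll <- synthProteinCollection(seed = 5)
  tr <- coll$truth
  for (i in seq_len(nrow(tr))) {
    if (tr$category[i] %in% c("multiDomain", "positive")) {
      res <- predictSignalPeptide(coll$proteins[[tr$id[i]]])
      expect_true(res$present)
      expect_equal(res$cleavagePos, 19L)
    } else if (tr$category[i] %in% c("noMotifs", "noSignalPeptide")) {
      expect_false(predictSignalPeptide(coll$proteins[[tr$id[i]]])$present)
    }
  }
  # degenerate inputs
  expect_equal(predictSignalPeptide("MKK")$reason, "too short")
  expect_false(predictSignalPeptide(
    paste0("MDDEEDDEE", strrep("DE", 20)))$present)
  # an external call overrides the heuristic
  ext <- predictSignalPeptide(strrep("G", 40), spEnd = 31)
  expect_true(ext$present)
  expect_equal(ext$cleavagePos, 31L)
})

test_that("cascade funnel counts are monotone and order-insensitive", {
  coll <- synthProteinCollection(seed = 21)
  rep1 <- runCascade(coll$proteins, coll$truth[, c("id", "family")])
  f <- funnel(rep1)
  expect_true(all(diff(f$surviving) <= 0))
  v <- verdicts(rep1)
  # the final set is the intersection of the per-filter predicate sets,
  # so it cannot depend on the order the filters are applied in
  byIntersection <- v$id[v$familyCE4 & v$motifsPresent & v$complete &
                           v$signalPeptide & v$singleDomain]
  expect_identical(v$id[v$candidate], byIntersection)
  # full annotations (domain counts, external SP calls) give the same
  # final candidate as the sequence heuristics
  rep2 <- runCascade(coll$proteins, coll$truth)
  expect_identical(verdicts(rep2)$id[verdicts(rep2)$candidate],
                   v$id[v$candidate])
})

test_that("empty collections and annotation overrides behave", {
  rep0 <- runCascade(character())
  expect_true(all(funnel(rep0)$surviving == 0))
  # completeness annotation overrides the sequence heuristic
  seqs <- c(x = paste0("M", strrep("G", 100)))
  ann <- data.frame(id = "x", complete_gene = FALSE)
  expect_false(verdicts(runCascade(seqs, ann))$complete)
  expect_true(verdicts(runCascade(seqs))$complete)
})
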