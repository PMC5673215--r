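# Independent oracles used across the suite.  Deliberately written
# without the package's own matching/compilation machinery.

# brute-force motif matcher: parse the restricted syntax into a list of
# allowed residue sets, then check every start position by set membership
bruteMotifHits <- function(pattern, sequence) {
  chars <- strsplit(pattern, "")[[1L]]
  sets <- list()
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1L]
      sets[[length(sets) + 1L]] <- chars[(i + 1L):(j - 1L)]
      i <- j + 1L
    } else if (chars[i] == "x") {
      sets <- c(sets, list(NULL))  # wildcard marker
      i <- i + 1L
    } else {
      sets[[length(sets) + 1L]] <- chars[i]
      i <- i + 1L
    }
  }
  v <- strsplit(sequence, "")[[1L]]
  L <- length(sets)
  n <- length(v)
  if (n < L) return(integer())
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    if (is.null(sets[[j]])) next
    ok <- ok & v[seq_len(n - L + 1L) + j - 1L] %in% sets[[j]]
  }
  which(ok)
}

# differential-ladder oracle: reconstruct an acetylation pattern from a
# noiseless Y-only ladder by reading the consecutive m/z differences
# (203.0794 = A, 161.0688 = D), right-to-left
ladderReadPattern <- function(yMz, massA = 203.0794, massD = 161.0688,
                              yConst = 210.0793 + 2.0157 + 1.00728) {
  yMz <- sort(yMz)
  first <- yMz[1L] - yConst
  res <- if (abs(first - massA) < abs(first - massD)) "A" else "D"
  if (length(yMz) > 1L) {
    for (d in diff(yMz)) {
      res <- c(if (abs(d - massA) < abs(d - massD)) "A" else "D", res)
    }
  }
  paste0(res, collapse = "")
}

# all 2^dp A/D strings, enumerated independently of the package
allPatternsOracle <- function(dp) {
  apply(as.matrix(expand.grid(rep(list(c("A", "D")), dp))), 1L,
        paste0, collapse = "")
}
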