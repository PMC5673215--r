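#' Rank acetylation patterns against an MS2 spectrum
#'
#' Enumerates every positional arrangement of a fixed GlcNAc/GlcN
#' composition, predicts its Y (and B) fragment ladder, and scores each
#' arrangement by the share of total MS2 intensity its ladder explains.
#' Y ions carry the full weight; peaks explained only by B ions
#' contribute with weight \code{bWeight} (B ions corroborate, the
#' label-retaining Y ladder carries the sequence information).  Ties are
#' broken lexicographically; patterns are returned in descending score
#' order.
#'
#' @param spectrum an MS2 \linkS4class{Spectrum}
#' @param nA,nD composition: number of GlcNAc (A) and GlcN (D) units
#' @param table a \linkS4class{MassTable}
#' @param tol peak-match tolerance in m/z units
#' @param bWeight weight of B-only evidence in the score (default 0.25)
#' @param label reducing-end label of the candidate patterns
#' @param checkPrecursor if TRUE (default) and the spectrum has a
#'   precursor m/z, require it to agree with the composition within
#'   \code{tol}
#' @return data.frame with columns pattern, score, explainedFraction,
#'   nMatched, ordered by descending score; the per-pattern ion/peak
#'   match tables are attached as \code{attr(, "matches")}
#' @examples
#' sp <- synthSpectrum(c("AADAA" = 1), noise = spectrumNoise(seed = 1))
#' rankPatterns(sp, nA = 4, nD = 1)
#' @export
rankPatterns <- function(spectrum, nA, nD, table = massTable(), tol = 0.5,
                         bWeight = 0.25, label = "AMAC",
                         checkPrecursor = TRUE) {
  stopifnot(is(spectrum, "Spectrum"), nA >= 0, nD >= 0, nA + nD >= 1)
  if (checkPrecursor && !is.na(spectrum@precursorMz)) {
    ref <- chosPattern(paste0(strrep("A", nA), strrep("D", nD)),
                       label = label)
    expected <- ionMz(ref, table)
    if (abs(expected - spectrum@precursorMz) > tol)
      stop("precursor m/z ", format(spectrum@precursorMz),
           " inconsistent with composition A", nA, "D", nD,
           " (expected ", format(expected, digits = 7), " within ", tol, ")")
  }
  pats <- compositionPatterns(nA, nD)
  pk <- spectrum@peaks
  total <- sum(pk$intensity)
  matches <- vector("list", length(pats))
  names(matches) <- pats
  score <- explained <- numeric(length(pats))
  nMatched <- integer(length(pats))
  for (i in seq_along(pats)) {
    p <- chosPattern(pats[i], label = label)
    ions <- fragmentLadder(p, ionTypes = c("Y", "B"), table = table)
    m <- matchPeaks(spectrum, ions, tol = tol)
    matches[[i]] <- m
    nMatched[i] <- nrow(m)
    if (total > 0 && nrow(m)) {
      peakKey <- match(m$peakMz, pk$mz)
      anyPeaks <- unique(peakKey)
      yPeaks <- unique(peakKey[m$ionType == "Y"])
      bOnly <- setdiff(anyPeaks, yPeaks)
      explained[i] <- sum(pk$intensity[anyPeaks]) / total
      score[i] <- (sum(pk$intensity[yPeaks]) +
                   bWeight * sum(pk$intensity[bOnly])) / total
    }
  }
  ## descending score; lexicographic (ascending) pattern string on ties
  o <- order(-score, pats)
  out <- data.frame(pattern = pats[o], score = score[o],
                    explainedFraction = explained[o],
                    nMatched = nMatched[o])
  rownames(out) <- NULL
  attr(out, "matches") <- matches[o]
  out
}

#' Per-position deacetylation support from ranked patterns
#'
#' Converts a pattern ranking into per-position deacetylation
#' frequencies: pattern weights are the scores sharpened by an exponent
#' gamma and normalized, and f_i is the weighted frequency of D at
#' position i (non-reducing to reducing end).  When every score is zero
#' the frequencies are uniform (nD/DP) and the ambiguity flag is set; the
#' flag is also set when the top two scores differ by less than epsilon,
#' i.e. when the spectrum cannot resolve the leading isomers.
#'
#' @param scores data.frame from \code{\link{rankPatterns}} (single
#'   composition)
#' @param gamma sharpening exponent for the score weights (default 4)
#' @param epsilon ambiguity threshold on the top-two score gap
#'   (default 0.05, absolute score units)
#' @return list with elements \code{f} (numeric, length DP),
#'   \code{ambiguity} (logical), \code{weights} (named numeric)
#' @export
positionalSupport <- function(scores, gamma = 4, epsilon = 0.05) {
  stopifnot(is.data.frame(scores), nrow(scores) >= 1L,
            all(c("pattern", "score") %in% names(scores)))
  dp <- unique(nchar(scores$pattern))
  if (length(dp) != 1L)
    stop("all patterns must share one composition (mixed DP found)")
  mat <- do.call(rbind, strsplit(scores$pattern, "")) == "D"
  s <- scores$score
  if (all(s == 0)) {
    w <- rep(1 / length(s), length(s))
    ambiguity <- TRUE
  } else {
    w <- s^gamma
    w <- w / sum(w)
    top <- sort(s, decreasing = TRUE)
    ambiguity <- length(s) > 1L && (top[1L] - top[2L]) < epsilon
  }
  f <- as.numeric(w %*% mat)
  names(f) <- paste0("pos", seq_len(dp))
  names(w) <- scores$pattern
  list(f = f, ambiguity = ambiguity, weights = w)
}

#' Diagnose the acetylation state of the chain ends from an MS2 spectrum
#'
#' Reports the evidence for acetylated vs deacetylated termini of an
#' AMAC-labeled CHOS pool of fixed composition: the Y1 ions (GlcNAc-AMAC
#' at m/z 416.18 vs GlcN-AMAC at 374.17, monoisotopic) read out the
#' reducing end, and the Y_(DP-1) ions read out the non-reducing end —
#' losing a D from the non-reducing terminus leaves a Y_(DP-1) fragment
#' of composition (nA, nD-1), losing an A leaves (nA-1, nD).
#'
#' @param spectrum an MS2 \linkS4class{Spectrum}
#' @param nA,nD composition of the precursor pool
#' @param table a \linkS4class{MassTable}
#' @param tol peak-match tolerance in m/z units
#' @return list with a \code{table} (one row per diagnostic ion:
#'   ion, interpretation, mz, present, intensity, relIntensity) and the
#'   summary calls \code{reducingEnd} and \code{nonReducingEndDeacetylated}
#' @export
endDiagnostics <- function(spectrum, nA, nD, table = massTable(), tol = 0.5) {
  stopifnot(is(spectrum, "Spectrum"), nA + nD >= 2L)
  labelAdd <- table@masses[["AMAC"]] + table@masses[["H2"]] +
    table@masses[["proton"]]
  compMz <- function(a, d)
    a * table@masses[["A"]] + d * table@masses[["D"]] + labelAdd
  rows <- data.frame(
    ion = c("Y1", "Y1", paste0("Y", nA + nD - 1L), paste0("Y", nA + nD - 1L)),
    interpretation = c("reducing end A (GlcNAc-AMAC)",
                       "reducing end D (GlcN-AMAC)",
                       "non-reducing end A lost",
                       "non-reducing end D lost"),
    composition = c("A1", "D1",
                    paste0("A", nA - 1L, "D", nD),
                    paste0("A", nA, "D", nD - 1L)),
    mz = c(compMz(1L, 0L), compMz(0L, 1L),
           if (nA >= 1L) compMz(nA - 1L, nD) else NA_real_,
           if (nD >= 1L) compMz(nA, nD - 1L) else NA_real_))
  rows <- rows[!is.na(rows$mz), , drop = FALSE]
  pk <- spectrum@peaks
  inten <- vapply(rows$mz, function(m) {
    if (!nrow(pk)) return(0)
    d <- abs(pk$mz - m)
    j <- which.min(d)
    if (d[j] <= tol) pk$intensity[j] else 0
  }, numeric(1L))
  rows$present <- inten > 0
  rows$intensity <- inten
  rows$relIntensity <- if (max(inten) > 0) inten / max(inten) else inten
  rownames(rows) <- NULL
  redA <- rows$intensity[rows$interpretation == "reducing end A (GlcNAc-AMAC)"]
  redD <- rows$intensity[rows$interpretation == "reducing end D (GlcN-AMAC)"]
  reducingEnd <- if (redA == 0 && redD == 0) "no Y1 evidence"
    else if (redA >= redD) "predominantly acetylated"
    else "predominantly deacetylated"
  dLost <- rows$intensity[rows$interpretation == "non-reducing end D lost"]
  list(table = rows,
       reducingEnd = reducingEnd,
       nonReducingEndDeacetylated = length(dLost) > 0 && dLost > 0)
}
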