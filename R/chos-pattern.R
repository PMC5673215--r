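#' Construct a chitooligosaccharide acetylation pattern
#'
#' @param residues pattern string over \{A, D\}, non-reducing end first,
#'   e.g. \code{"AADAA"}.  The serialized form \code{"AADAA+AMAC"} is also
#'   accepted and sets the label.
#' @param label reducing-end label, \code{"none"} (default) or \code{"AMAC"}
#' @return a \linkS4class{ChosPattern}
#' @examples
#' chosPattern("AADAA", label = "AMAC")
#' chosPattern("AAD+AMAC")
#' @name chosPattern
#' @aliases residues chosLabel dpOf
#' @export
chosPattern <- function(residues, label = c("none", "AMAC")) {
  stopifnot(is.character(residues), length(residues) == 1L)
  if (grepl("+", residues, fixed = TRUE)) {
    parts <- strsplit(residues, "+", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || parts[2L] != "AMAC")
      stop("unrecognized pattern suffix in ", sQuote(residues),
           "; only '+AMAC' is supported")
    residues <- parts[1L]
    label <- "AMAC"
  } else {
    label <- match.arg(label)
  }
  new("ChosPattern", residues = toupper(residues), label = label)
}

#' @rdname chosPattern
#' @param x a ChosPattern
#' @export
setMethod("residues", "ChosPattern", function(x) x@residues)

#' @rdname chosPattern
#' @export
setMethod("chosLabel", "ChosPattern", function(x) x@label)

#' @rdname chosPattern
#' @export
setMethod("dpOf", "ChosPattern", function(x) nchar(x@residues))

setMethod("show", "ChosPattern", function(object) {
  cat("ChosPattern (non-reducing end -> reducing end): ",
      patternString(object), "\n", sep = "")
  st <- patternStats(object)
  cat("  DP ", st$dp, " | nA ", st$nA, " | nD ", st$nD,
      " | F_A ", format(st$fA, digits = 3), "\n", sep = "")
})

#' Serialize a pattern as a plain string
#'
#' Uses the \code{"AADAA+AMAC"} suffix convention for labeled patterns.
#' @param pattern a \linkS4class{ChosPattern}
#' @return character string
#' @export
patternString <- function(pattern) {
  stopifnot(is(pattern, "ChosPattern"))
  if (pattern@label == "AMAC") paste0(pattern@residues, "+AMAC")
  else pattern@residues
}

#' Composition and acetylation fraction of a pattern
#'
#' Counts GlcNAc (A) and GlcN (D) units and the fraction of acetylation
#' F_A = nA / DP.
#'
#' @param pattern a \linkS4class{ChosPattern}
#' @return list with elements \code{dp}, \code{nA}, \code{nD}, \code{fA}
#' @examples
#' patternStats(chosPattern("AADAA"))   # nA 4, nD 1, F_A 0.8
#' @name patternStats
#' @export
setMethod("patternStats", "ChosPattern", function(pattern) {
  v <- strsplit(pattern@residues, "")[[1L]]
  nA <- sum(v == "A")
  nD <- sum(v == "D")
  list(dp = nA + nD, nA = nA, nD = nD, fA = nA / (nA + nD))
})

## all 2^dp patterns of a given degree of polymerization
allPatterns <- function(dp, label = "none") {
  stopifnot(dp >= 1L, dp <= 12L)
  grid <- expand.grid(rep(list(c("A", "D")), dp), stringsAsFactors = FALSE)
  apply(as.matrix(grid), 1L, paste0, collapse = "")
}

## all C(dp, nD) arrangements of a fixed composition, lexicographic order
compositionPatterns <- function(nA, nD) {
  dp <- nA + nD
  if (nD == 0L) return(strrep("A", dp))
  if (nA == 0L) return(strrep("D", dp))
  idx <- utils::combn(dp, nD, simplify = FALSE)
  pats <- vapply(idx, function(i) {
    v <- rep("A", dp); v[i] <- "D"; paste0(v, collapse = "")
  }, character(1L))
  sort(pats)
}
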