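## Kyte-Doolittle hydropathy index
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2, X = 0, "*" = 0)

#' Heuristic Sec signal-peptide prediction
#'
#' A transparent three-clause stand-in for a dedicated signal-peptide
#' predictor, modeling the canonical tripartite architecture:
#' \itemize{
#'   \item n-region: at least one K or R within residues 2-6;
#'   \item h-region: some window of 8 contiguous residues within
#'     positions 6-25 with mean Kyte-Doolittle hydropathy >= 1.5;
#'   \item c-region: a cleavage site at the first position 16-35 whose
#'     -3 and -1 residues are both small (A, G, S, C or T; the von
#'     Heijne small-residue rule), cleavage occurring after that
#'     position.
#' }
#' An external predictor call supplied via \code{spEnd} always overrides
#' the heuristic.
#'
#' @param sequence amino-acid string, length >= 25 for the heuristic
#' @param spEnd optional externally predicted signal-peptide end
#'   (cleavage after this residue); when given, the heuristic is bypassed
#' @return list with \code{present}, \code{cleavagePos} (last residue of
#'   the signal peptide, or NA) and \code{reason}
#' @export
predictSignalPeptide <- function(sequence, spEnd = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!is.null(spEnd) && !is.na(spEnd)) {
    return(list(present = TRUE, cleavagePos = as.integer(spEnd),
                reason = "external prediction"))
  }
  n <- nchar(sequence)
  if (n < 25L)
    return(list(present = FALSE, cleavagePos = NA_integer_,
                reason = "too short"))
  v <- strsplit(sequence, "")[[1L]]
  nRegion <- any(v[2:6] %in% c("K", "R"))
  if (!nRegion)
    return(list(present = FALSE, cleavagePos = NA_integer_,
                reason = "no positively charged n-region"))
  kd <- .KD[v]
  kd[is.na(kd)] <- 0
  hi <- min(25L, n)
  winStarts <- 6:(hi - 7L)
  hRegion <- length(winStarts) >= 1L &&
    any(vapply(winStarts, function(s) mean(kd[s:(s + 7L)]), numeric(1L))
        >= 1.5)
  if (!hRegion)
    return(list(present = FALSE, cleavagePos = NA_integer_,
                reason = "no hydrophobic h-region"))
  small <- c("A", "G", "S", "C", "T")
  for (c in 16:min(35L, n - 1L)) {
    if (v[c] %in% small && v[c - 2L] %in% small)
      return(list(present = TRUE, cleavagePos = c,
                  reason = "heuristic (n/h/c regions found)"))
  }
  list(present = FALSE, cleavagePos = NA_integer_,
       reason = "no small-residue cleavage site in 16-35")
}
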