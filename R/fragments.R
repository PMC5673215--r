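#' Theoretical glycosidic fragment ladder of a labeled CHOS
#'
#' Enumerates singly-protonated Y- and B-type glycosidic cleavage ions for
#' a chitooligosaccharide pattern.  Y_k ions retain the reducing end and
#' therefore the AMAC label: m/z = sum of the last k residue masses +
#' AMAC + H2 + proton.  B_k ions are the unlabeled non-reducing-end
#' prefixes (oxocarbenium): m/z = sum of the first k residue masses +
#' proton.  Y runs k = 1..DP (Y_DP is the intact precursor); B runs
#' k = 1..DP-1.
#'
#' @param pattern an AMAC-labeled \linkS4class{ChosPattern} (label
#'   required when Y ions are requested)
#' @param ionTypes subset of \code{c("Y", "B")}
#' @param table a \linkS4class{MassTable}
#' @return data.frame with columns ionType, k, subPattern, mz
#' @examples
#' fragmentLadder(chosPattern("AADAA", label = "AMAC"))
#' @export
fragmentLadder <- function(pattern, ionTypes = c("Y", "B"),
                           table = massTable()) {
  stopifnot(is(pattern, "ChosPattern"))
  ionTypes <- match.arg(ionTypes, c("Y", "B"), several.ok = TRUE)
  if ("Y" %in% ionTypes && pattern@label != "AMAC")
    stop("Y ions require an AMAC-labeled pattern (the label marks the ",
         "reducing end that Y fragments retain)")
  v <- strsplit(pattern@residues, "")[[1L]]
  dp <- length(v)
  rows <- list()
  if ("Y" %in% ionTypes) {
    labelAdd <- table@masses[["AMAC"]] + table@masses[["H2"]]
    for (k in seq_len(dp)) {
      sub <- paste0(v[(dp - k + 1L):dp], collapse = "")
      mz <- residueMassSum(sub, table) + labelAdd + table@masses[["proton"]]
      rows[[length(rows) + 1L]] <-
        data.frame(ionType = "Y", k = k, subPattern = sub, mz = mz)
    }
  }
  if ("B" %in% ionTypes && dp > 1L) {
    for (k in seq_len(dp - 1L)) {
      sub <- paste0(v[seq_len(k)], collapse = "")
      mz <- residueMassSum(sub, table) + table@masses[["proton"]]
      rows[[length(rows) + 1L]] <-
        data.frame(ionType = "B", k = k, subPattern = sub, mz = mz)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Match theoretical fragment ions against spectrum peaks
#'
#' Each ion is paired with the nearest peak lying within \code{tol};
#' unmatched ions are dropped.  One peak may support several isobaric
#' ions (positional isomers share fragment masses; exclusive assignment
#' would silently discard evidence).
#'
#' @param spectrum a \linkS4class{Spectrum}
#' @param ions data.frame from \code{\link{fragmentLadder}}
#' @param tol match tolerance in m/z units
#' @return the matched subset of \code{ions} with extra columns
#'   \code{peakMz}, \code{peakIntensity}, \code{deltaMz}
#' @export
matchPeaks <- function(spectrum, ions, tol = 0.5) {
  stopifnot(is(spectrum, "Spectrum"), tol > 0)
  pk <- spectrum@peaks
  if (!nrow(pk) || is.null(ions) || !nrow(ions)) {
    out <- cbind(ions[0, , drop = FALSE],
                 peakMz = numeric(), peakIntensity = numeric(),
                 deltaMz = numeric())
    return(out)
  }
  idx <- vapply(ions$mz, function(m) {
    d <- abs(pk$mz - m)
    j <- which.min(d)
    if (d[j] <= tol) j else NA_integer_
  }, integer(1L))
  keep <- !is.na(idx)
  out <- ions[keep, , drop = FALSE]
  out$peakMz <- pk$mz[idx[keep]]
  out$peakIntensity <- pk$intensity[idx[keep]]
  out$deltaMz <- out$peakMz - out$mz
  rownames(out) <- NULL
  out
}
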