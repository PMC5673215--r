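#' @import methods
NULL

#' ChosPattern: a chitooligosaccharide acetylation pattern
#'
#' An ordered string over the alphabet \{A, D\} describing the positional
#' arrangement of N-acetylglucosamine (A, GlcNAc) and glucosamine
#' (D, GlcN) units in a chitooligosaccharide, written from the
#' non-reducing end (left) to the reducing end (right).  The reducing end
#' may carry a 2-aminoacridone (AMAC) fluorophore attached by reductive
#' amination.
#'
#' @slot residues single character string over \{A, D\}, length 1--12
#' @slot label reducing-end label, one of \code{"none"} or \code{"AMAC"}
#' @export
setClass("ChosPattern",
  representation(residues = "character", label = "character"),
  prototype(residues = "A", label = "none"))

setValidity("ChosPattern", function(object) {
  msg <- character()
  if (length(object@residues) != 1L || is.na(object@residues))
    msg <- c(msg, "'residues' must be a single non-NA string")
  else {
    n <- nchar(object@residues)
    if (n < 1L || n > 12L)
      msg <- c(msg, "degree of polymerization must be between 1 and 12")
    if (grepl("[^AD]", object@residues))
      msg <- c(msg, "residues must be drawn from the alphabet {A, D}")
  }
  if (length(object@label) != 1L || !object@label %in% c("none", "AMAC"))
    msg <- c(msg, "label must be \"none\" or \"AMAC\"")
  if (length(msg)) msg else TRUE
})

#' MassTable: residue and adduct masses for CHOS mass arithmetic
#'
#' Holds the residue masses of GlcNAc (A) and GlcN (D) together with the
#' small-molecule masses needed for neutral-mass and m/z computation of
#' (optionally AMAC-labeled) chitooligosaccharides.  All masses in Da.
#'
#' @slot convention \code{"monoisotopic"} or \code{"average"}
#' @slot masses named numeric vector with elements \code{A}, \code{D},
#'   \code{water}, \code{H2}, \code{proton}, \code{acetyl}, \code{AMAC}
#' @export
setClass("MassTable",
  representation(convention = "character", masses = "numeric"))

setValidity("MassTable", function(object) {
  msg <- character()
  need <- c("A", "D", "water", "H2", "proton", "acetyl", "AMAC")
  if (!all(need %in% names(object@masses)))
    msg <- c(msg, paste("masses must contain:", paste(need, collapse = ", ")))
  else {
    if (any(object@masses[need] <= 0)) msg <- c(msg, "all masses must be > 0")
    if (abs((object@masses[["A"]] - object@masses[["D"]]) -
            object@masses[["acetyl"]]) > 5e-3)
      msg <- c(msg, "mass(A) - mass(D) must equal the acetyl delta")
  }
  if (!object@convention %in% c("monoisotopic", "average"))
    msg <- c(msg, "convention must be \"monoisotopic\" or \"average\"")
  if (length(msg)) msg else TRUE
})

#' Spectrum: a mass-spectrometric peak list
#'
#' A single MS1 or MS2 scan: a peak table (m/z, intensity) sorted by
#' ascending m/z, plus the precursor m/z for MS2 scans.
#'
#' @slot precursorMz precursor ion m/z (NA for MS1)
#' @slot msLevel integer, 1 or 2
#' @slot peaks data.frame with numeric columns \code{mz} and
#'   \code{intensity}, sorted ascending by \code{mz}
#' @export
setClass("Spectrum",
  representation(precursorMz = "numeric", msLevel = "integer",
                 peaks = "data.frame"))

setValidity("Spectrum", function(object) {
  msg <- character()
  pk <- object@peaks
  if (!all(c("mz", "intensity") %in% names(pk)))
    msg <- c(msg, "peaks must have columns 'mz' and 'intensity'")
  else {
    if (nrow(pk) && any(pk$mz <= 0)) msg <- c(msg, "peak m/z must be > 0")
    if (nrow(pk) && any(pk$intensity < 0))
      msg <- c(msg, "peak intensities must be >= 0")
    if (is.unsorted(pk$mz)) msg <- c(msg, "peaks must be sorted by m/z")
  }
  if (!object@msLevel %in% c(1L, 2L)) msg <- c(msg, "msLevel must be 1 or 2")
  if (object@msLevel == 2L && is.na(object@precursorMz))
    msg <- c(msg, "MS2 spectra require a precursor m/z")
  if (length(msg)) msg else TRUE
})

#' RateModel: position-specific deacetylation rate constants
#'
#' First-order rate constants k_i (s^-1) for deacetylation at each sugar
#' position i = 1..DP (non-reducing to reducing end), with an optional
#' multiplicative neighbor penalty applied once per already-deacetylated
#' adjacent residue.  A penalty of 1 makes positions independent.
#'
#' @slot rates numeric vector of per-position rate constants, all >= 0
#' @slot neighborPenalty single numeric in (0, 1]
#' @export
setClass("RateModel",
  representation(rates = "numeric", neighborPenalty = "numeric"))

setValidity("RateModel", function(object) {
  msg <- character()
  if (!length(object@rates) || anyNA(object@rates) || any(object@rates < 0))
    msg <- c(msg, "rates must be non-negative and non-missing")
  if (length(object@rates) > 12L)
    msg <- c(msg, "at most 12 positions supported")
  p <- object@neighborPenalty
  if (length(p) != 1L || is.na(p) || p <= 0 || p > 1)
    msg <- c(msg, "neighborPenalty must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' ScreenReport: result of the CE4 candidate-selection funnel
#'
#' Per-protein filter verdicts and the stage-by-stage survivor counts of
#' the screening cascade (family tag, five-motif scan, gene completeness,
#' signal peptide, single domain).
#'
#' @slot verdicts data.frame, one row per protein: id, per-filter logicals,
#'   motif hit positions, and the final \code{candidate} call
#' @slot funnel data.frame with columns \code{filter} and \code{surviving}
#' @export
setClass("ScreenReport",
  representation(verdicts = "data.frame", funnel = "data.frame"))

setValidity("ScreenReport", function(object) {
  msg <- character()
  if (!all(c("filter", "surviving") %in% names(object@funnel)))
    msg <- c(msg, "funnel must have columns 'filter' and 'surviving'")
  else if (nrow(object@funnel) > 1 && is.unsorted(-object@funnel$surviving))
    msg <- c(msg, "funnel counts must be monotone non-increasing")
  if (length(msg)) msg else TRUE
})
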