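#' Build one activity-assay record
#'
#' Raw inputs of a single-point deacetylase activity assay: the substrate
#' specification (either molar concentration plus acetyl groups per
#' molecule, or mass concentration plus residue molar mass plus fraction
#' of acetylation — or a directly supplied ASAR), the measured acetate
#' release, and the incubation conditions.
#'
#' @param substrate substrate name
#' @param acetateUM released acetic acid, mean, in uM
#' @param timeMin incubation time in minutes (default 30)
#' @param enzymeUM enzyme concentration in uM (default 0.3, i.e. 300 nM)
#' @param volumeML reaction volume in ml (default 0.1)
#' @param cvPercent coefficient of variation of the acetate measurement
#' @param concUM molar substrate concentration in uM (molar spec)
#' @param acetylsPerMolecule acetyl groups per substrate molecule
#' @param massConcMgMl substrate mass concentration in mg/ml (mass spec)
#' @param residueMassGMol sugar-residue molar mass in g/mol (mass spec)
#' @param fractionAcetylated fraction of residues acetylated, in (0, 1]
#' @param asarUM directly supplied ASAR in uM, overriding both specs
#'   (for substrates whose residue-mass assumptions are not available)
#' @return one-row data.frame
#' @export
activityAssay <- function(substrate, acetateUM, timeMin = 30,
                          enzymeUM = 0.3, volumeML = 0.1,
                          cvPercent = NA_real_,
                          concUM = NA_real_, acetylsPerMolecule = NA_real_,
                          massConcMgMl = NA_real_,
                          residueMassGMol = NA_real_,
                          fractionAcetylated = NA_real_,
                          asarUM = NA_real_) {
  stopifnot(acetateUM >= 0, timeMin > 0, enzymeUM > 0, volumeML > 0)
  data.frame(substrate = substrate, acetateUM = acetateUM,
             timeMin = timeMin, enzymeUM = enzymeUM, volumeML = volumeML,
             cvPercent = cvPercent, concUM = concUM,
             acetylsPerMolecule = acetylsPerMolecule,
             massConcMgMl = massConcMgMl,
             residueMassGMol = residueMassGMol,
             fractionAcetylated = fractionAcetylated, asarUM = asarUM,
             stringsAsFactors = FALSE)
}

#' Amount of substrate as acetyl-group concentration (ASAR)
#'
#' ASAR expresses the substrate amount as the molar concentration of
#' acetyl groups.  Molar specification: concentration x acetyl groups
#' per molecule.  Mass specification: mass concentration (g/L) divided
#' by the residue molar mass (g/mol), times 1e6 (to uM), times the
#' fraction of acetylation.  Computed values are reported to 3
#' significant figures; a directly supplied \code{asarUM} is passed
#' through unchanged.
#'
#' @param assay one-row data.frame from \code{\link{activityAssay}}
#' @return ASAR in uM
#' @examples
#' computeAsar(activityAssay("(GlcNAc)5", 95.8, concUM = 2000,
#'                           acetylsPerMolecule = 5))        # 10000
#' computeAsar(activityAssay("alpha-chitin", 0.8, massConcMgMl = 5,
#'                           residueMassGMol = 203.19,
#'                           fractionAcetylated = 1))        # 24600
#' @export
computeAsar <- function(assay) {
  if (!is.na(assay$asarUM)) return(assay$asarUM)
  if (!is.na(assay$concUM) && !is.na(assay$acetylsPerMolecule))
    return(signif(assay$concUM * assay$acetylsPerMolecule, 3))
  if (!is.na(assay$massConcMgMl)) {
    if (is.na(assay$residueMassGMol) || is.na(assay$fractionAcetylated))
      stop("mass specification requires residueMassGMol and ",
           "fractionAcetylated for substrate ", sQuote(assay$substrate))
    ## mg/ml = g/L; mol/L * 1e6 = uM
    return(signif(assay$massConcMgMl / assay$residueMassGMol * 1e6 *
                  assay$fractionAcetylated, 3))
  }
  stop("incomplete substrate specification for ", sQuote(assay$substrate))
}

#' Derived activity metrics for one assay
#'
#' From the raw inputs computes: deacetylation degree (%) = 100 x
#' acetate / ASAR; acetate release rate (nmol/min) = acetate (uM) x
#' volume (ml) / time (min); apparent rate constant (s^-1) = acetate
#' (uM) / (time (s) x enzyme concentration (uM)).
#'
#' @param assay one-row data.frame from \code{\link{activityAssay}}
#' @return one-row data.frame: substrate, asarUM, acetateUM, cvPercent,
#'   degreePercent, releaseRate, kApp (unrounded)
#' @examples
#' deriveMetrics(activityAssay("(GlcNAc)5", 95.8, concUM = 2000,
#'                             acetylsPerMolecule = 5))
#' @export
deriveMetrics <- function(assay) {
  if (assay$timeMin <= 0 || assay$enzymeUM <= 0)
    stop("time and enzyme concentration must be positive")
  asar <- computeAsar(assay)
  data.frame(substrate = assay$substrate,
             asarUM = asar,
             acetateUM = assay$acetateUM,
             cvPercent = assay$cvPercent,
             degreePercent = 100 * assay$acetateUM / asar,
             releaseRate = assay$acetateUM * assay$volumeML / assay$timeMin,
             kApp = assay$acetateUM / (assay$timeMin * 60 * assay$enzymeUM),
             stringsAsFactors = FALSE)
}

## report formatting: degrees span four orders of magnitude, so the
## decimal places follow the value's magnitude; rates and rate constants
## are fixed at two decimals
formatDegree <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) NA_character_
    else if (v >= 10) sprintf("%.1f", v)
    else if (v >= 0.01) sprintf("%.2f", v)
    else sprintf("%.3f", v)
  }, character(1L))
}

#' Reconstruct a full activity table
#'
#' Applies \code{\link{deriveMetrics}} to every assay and appends
#' report-formatted columns (degree per magnitude, rate and apparent
#' rate constant at two decimals).
#'
#' @param assays data.frame of assay rows (one per substrate), as built
#'   by \code{rbind}-ing \code{\link{activityAssay}} calls
#' @return data.frame, one row per assay, with both numeric and
#'   formatted derived columns
#' @examples
#' reproduceTable(chitinDeacetylaseAssays())
#' @export
reproduceTable <- function(assays) {
  stopifnot(is.data.frame(assays), nrow(assays) >= 1L)
  out <- do.call(rbind, lapply(seq_len(nrow(assays)), function(i)
    deriveMetrics(assays[i, , drop = FALSE])))
  out$degreeFmt <- formatDegree(out$degreePercent)
  out$releaseRateFmt <- sprintf("%.2f", out$releaseRate)
  out$kAppFmt <- sprintf("%.2f", out$kApp)
  rownames(out) <- NULL
  out
}

#' Published activity panel of a marine bacterial CE4 chitin deacetylase
#'
#' Raw inputs of the ten-substrate activity assay of a cold-adapted CE4
#' chitin deacetylase from a marine \emph{Arthrobacter} isolate:
#' chitooligosaccharides (GlcNAc)1-6 at 2 mM, chitosan, alpha- and
#' beta-chitin and acetyl xylan at 5 mg/ml, each incubated with 300 nM
#' enzyme for 30 min.  ASAR values for chitosan (F_A = 0.64) and acetyl
#' xylan (acetylation roughly 50%) are carried as direct inputs because
#' their residue-mass assumptions are not published; the chitin ASAR is
#' recomputed from 5 mg/ml assuming one acetyl per 203.19 g/mol residue.
#'
#' @return data.frame of assay rows suitable for
#'   \code{\link{reproduceTable}}
#' @export
chitinDeacetylaseAssays <- function() {
  chos <- do.call(rbind, Map(function(n, acet, cv) {
    nm <- if (n == 1L) "GlcNAc" else sprintf("(GlcNAc)%d", n)
    activityAssay(nm, acetateUM = acet, cvPercent = cv,
                  concUM = 2000, acetylsPerMolecule = n)
  }, 1:6, c(0.0, 0.1, 11.9, 39.8, 95.8, 39.4),
     c(0.0, 14.5, 2.6, 2.8, 7.7, 0.2)))
  rbind(chos,
        activityAssay("chitosan", 85.4, cvPercent = 1.4, asarUM = 16000),
        activityAssay("alpha-chitin", 0.8, cvPercent = 6.4,
                      massConcMgMl = 5, residueMassGMol = 203.19,
                      fractionAcetylated = 1),
        activityAssay("beta-chitin", 1.4, cvPercent = 1.9,
                      massConcMgMl = 5, residueMassGMol = 203.19,
                      fractionAcetylated = 1),
        activityAssay("acetyl xylan", 1696.7, cvPercent = 3.1,
                      asarUM = 9000))
}
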