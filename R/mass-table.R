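## Elemental compositions behind the table:
##   GlcNAc residue  C8H13NO5   (dehydrated, in-chain)
##   GlcN residue    C6H11NO4
##   acetyl delta    C2H2O      (= mass(A) - mass(D))
##   AMAC            C13H10N2O  (2-aminoacridone)
## Reductive amination of the reducing end with AMAC removes the
## condensation water and the subsequent reduction adds H2, so a labeled
## oligomer weighs sum(residues) + AMAC + H2 instead of + H2O.
.MONO <- c(A = 203.0794, D = 161.0688, water = 18.0106, H2 = 2.0157,
           proton = 1.00728, acetyl = 42.0106, AMAC = 210.0793)
.AVG <- c(A = 203.194, D = 161.157, water = 18.015, H2 = 2.016,
          proton = 1.00728, acetyl = 42.037, AMAC = 210.236)

#' Mass table for CHOS mass arithmetic
#'
#' Residue masses of GlcNAc (A) and GlcN (D) plus water, H2, proton,
#' acetyl and AMAC masses, under the monoisotopic (default) or average
#' mass convention.
#'
#' @param convention \code{"monoisotopic"} (default) or \code{"average"}
#' @return a \linkS4class{MassTable}
#' @examples
#' massTable()
#' massTableJson(massTable())
#' @export
massTable <- function(convention = c("monoisotopic", "average")) {
  convention <- match.arg(convention)
  masses <- if (convention == "monoisotopic") .MONO else .AVG
  new("MassTable", convention = convention, masses = masses)
}

setMethod("show", "MassTable", function(object) {
  cat("MassTable (", object@convention, ", Da)\n", sep = "")
  print(round(object@masses, 4))
})

#' @rdname massTable
#' @param table a \linkS4class{MassTable}
#' @export
massTableJson <- function(table) {
  stopifnot(is(table, "MassTable"))
  jsonlite::toJSON(list(convention = table@convention,
                        masses = as.list(table@masses)),
                   auto_unbox = TRUE, digits = NA)
}

residueMassSum <- function(residueString, table) {
  v <- strsplit(residueString, "")[[1L]]
  bad <- setdiff(unique(v), c("A", "D"))
  if (length(bad))
    stop("unknown residue symbol(s): ", paste(bad, collapse = ", "))
  sum(table@masses[v])
}

#' Neutral mass of a chitooligosaccharide
#'
#' For an unlabeled oligomer the neutral mass is the sum of residue masses
#' plus one water.  For an AMAC-labeled oligomer (reductive amination at
#' the reducing end) it is the sum of residue masses plus AMAC plus H2:
#' the amination condenses out the reducing-end water and the reduction
#' adds two hydrogens, a net gain of 194.084 Da (monoisotopic) over the
#' unlabeled species.
#'
#' @param pattern a \linkS4class{ChosPattern}
#' @param table a \linkS4class{MassTable}
#' @param charge positive integer charge state (protonated species)
#' @return mass in Da (\code{neutralMass}) or m/z (\code{ionMz})
#' @examples
#' neutralMass(chosPattern("AAAAA"))                  # 1033.41
#' ionMz(chosPattern("A", label = "AMAC"))            # 416.18 (GlcNAc-AMAC)
#' ionMz(chosPattern("AADAA", label = "AMAC"))        # 1186.49
#' @name neutralMass
#' @aliases ionMz
#' @export
setMethod("neutralMass", "ChosPattern", function(pattern, table = massTable()) {
  stopifnot(is(table, "MassTable"))
  m <- residueMassSum(pattern@residues, table)
  if (pattern@label == "AMAC")
    m + table@masses[["AMAC"]] + table@masses[["H2"]]
  else
    m + table@masses[["water"]]
})

#' @rdname neutralMass
#' @export
setMethod("ionMz", "ChosPattern",
  function(pattern, table = massTable(), charge = 1L) {
    if (!is.numeric(charge) || length(charge) != 1L || charge < 1)
      stop("charge must be a positive integer")
    charge <- as.integer(charge)
    (neutralMass(pattern, table) + charge * table@masses[["proton"]]) / charge
  })

#' Infer CHOS compositions consistent with an observed m/z
#'
#' Enumerates all (DP, nA, nD) compositions within the given DP range
#' whose singly-protonated ion lies within \code{tol} of the observed
#' m/z, sorted by absolute mass error.
#'
#' @param mzObs observed m/z (singly protonated assumed)
#' @param dpRange integer vector; its range (within 1..12) is searched
#' @param label \code{"none"} or \code{"AMAC"}
#' @param table a \linkS4class{MassTable}
#' @param tol match tolerance in m/z units (default 0.5, unit-resolution
#'   ion-trap data)
#' @return data.frame with columns dp, nA, nD, mz, error
#' @examples
#' compositionFromMz(1186.6, dpRange = 5, label = "AMAC")   # A4 D1
#' compositionFromMz(1144.6, dpRange = 5, label = "AMAC")   # A3 D2
#' @export
compositionFromMz <- function(mzObs, dpRange = 1:12,
                              label = c("none", "AMAC"),
                              table = massTable(), tol = 0.5) {
  label <- match.arg(label)
  stopifnot(tol > 0, is.numeric(mzObs), length(mzObs) == 1L)
  dpRange <- as.integer(dpRange)
  if (!length(dpRange) || anyNA(dpRange))
    stop("dpRange must be a non-empty integer range")
  dps <- seq.int(min(dpRange), max(dpRange))
  if (min(dps) < 1L || max(dps) > 12L)
    stop("dpRange must lie within [1, 12]")
  out <- do.call(rbind, lapply(dps, function(dp) {
    nD <- 0:dp
    nA <- dp - nD
    base <- nA * table@masses[["A"]] + nD * table@masses[["D"]]
    add <- if (label == "AMAC")
      table@masses[["AMAC"]] + table@masses[["H2"]]
    else table@masses[["water"]]
    mz <- base + add + table@masses[["proton"]]
    data.frame(dp = dp, nA = nA, nD = nD, mz = mz, error = mz - mzObs)
  }))
  out <- out[abs(out$error) <= tol, , drop = FALSE]
  out <- out[order(abs(out$error)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
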