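#' Noise parameters for synthetic spectra
#'
#' @param mzJitterSd Gaussian m/z jitter standard deviation (Da)
#' @param nNoisePeaks number of uniform-random background peaks
#' @param noiseIntensityRange intensity range of background peaks
#'   (relative to a base peak intensity of 100)
#' @param mzRange m/z window for background peaks (ion-trap scan range)
#' @param seed integer RNG seed
#' @return list of noise parameters for \code{\link{synthSpectrum}}
#' @export
spectrumNoise <- function(mzJitterSd = 0, nNoisePeaks = 0L,
                          noiseIntensityRange = c(0.5, 5),
                          mzRange = c(150, 2000), seed = 1L) {
  stopifnot(mzJitterSd >= 0, nNoisePeaks >= 0L)
  list(mzJitterSd = mzJitterSd, nNoisePeaks = as.integer(nNoisePeaks),
       noiseIntensityRange = noiseIntensityRange, mzRange = mzRange,
       seed = seed)
}

#' Synthesize an MS2 spectrum of a CHOS isomer mixture
#'
#' Builds the theoretical Y (and, at reduced intensity, B) fragment
#' ladders of every pattern in the mixture, with intensities
#' proportional to the summed pattern frequencies (unit response
#' factors), then applies Gaussian m/z jitter and adds uniform-random
#' noise peaks.  Deterministic under a fixed seed.
#'
#' @param mixture named numeric vector: pattern string -> relative
#'   frequency; all patterns must share one DP (the \code{"+AMAC"}
#'   suffix is accepted and implied otherwise)
#' @param table a \linkS4class{MassTable}
#' @param noise a list from \code{\link{spectrumNoise}}
#' @param bIntensity relative intensity of B-ion peaks (default 0.3 of
#'   the corresponding Y intensity); 0 suppresses B ions
#' @return an MS2 \linkS4class{Spectrum} whose precursor is the intact
#'   labeled ion of the mixture's composition
#' @examples
#' synthSpectrum(c(AADAA = 0.5, ADAAA = 0.5),
#'               noise = spectrumNoise(mzJitterSd = 0.1, nNoisePeaks = 5))
#' @export
synthSpectrum <- function(mixture, table = massTable(),
                          noise = spectrumNoise(), bIntensity = 0.3) {
  stopifnot(is.numeric(mixture), length(mixture) >= 1L,
            !is.null(names(mixture)), all(mixture >= 0))
  pats <- lapply(names(mixture), function(s) {
    p <- chosPattern(s)
    if (p@label == "none") p@label <- "AMAC"
    p
  })
  dps <- vapply(pats, dpOf, integer(1L))
  if (length(unique(dps)) != 1L)
    stop("all mixture patterns must share one degree of polymerization")
  freq <- mixture / sum(mixture)
  ## accumulate ladder intensities; isobaric fragments merge
  acc <- new.env()
  add <- function(mz, inten) {
    key <- sprintf("%.6f", mz)
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + inten
  }
  for (i in seq_along(pats)) {
    if (freq[i] == 0) next
    lad <- fragmentLadder(pats[[i]], ionTypes = c("Y", "B"), table = table)
    for (j in seq_len(nrow(lad))) {
      w <- if (lad$ionType[j] == "Y") 1 else bIntensity
      if (w > 0) add(lad$mz[j], 100 * freq[i] * w)
    }
  }
  mz <- as.numeric(ls(acc))
  inten <- vapply(ls(acc), function(k) acc[[k]], numeric(1L))
  withSeed(noise$seed, {
    if (noise$mzJitterSd > 0)
      mz <- mz + stats::rnorm(length(mz), 0, noise$mzJitterSd)
    if (noise$nNoisePeaks > 0L) {
      mz <- c(mz, stats::runif(noise$nNoisePeaks, noise$mzRange[1L],
                               noise$mzRange[2L]))
      inten <- c(inten, stats::runif(noise$nNoisePeaks,
                                     noise$noiseIntensityRange[1L],
                                     noise$noiseIntensityRange[2L]))
    }
  })
  st <- patternStats(pats[[which.max(freq)]])
  prec <- ionMz(chosPattern(paste0(strrep("A", st$nA), strrep("D", st$nD)),
                            label = "AMAC"), table)
  newSpectrum(mz, inten, precursorMz = prec, msLevel = 2L)
}
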