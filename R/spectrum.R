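#' Construct a mass spectrum
#'
#' @param mz numeric vector of peak m/z values
#' @param intensity numeric vector of peak intensities
#' @param precursorMz precursor m/z (required for MS2)
#' @param msLevel 1 or 2
#' @return a \linkS4class{Spectrum}; peaks are sorted by ascending m/z
#' @name spectrum
#' @aliases peaks precursorMz msLevel
#' @export
newSpectrum <- function(mz, intensity, precursorMz = NA_real_, msLevel = 2L) {
  stopifnot(length(mz) == length(intensity))
  o <- order(mz)
  new("Spectrum", precursorMz = as.numeric(precursorMz),
      msLevel = as.integer(msLevel),
      peaks = data.frame(mz = as.numeric(mz)[o],
                         intensity = as.numeric(intensity)[o]))
}

#' @rdname spectrum
#' @param x a Spectrum
#' @export
setMethod("peaks", "Spectrum", function(x) x@peaks)

#' @rdname spectrum
#' @export
setMethod("precursorMz", "Spectrum", function(x) x@precursorMz)

#' @rdname spectrum
#' @export
setMethod("msLevel", "Spectrum", function(x) x@msLevel)

setMethod("show", "Spectrum", function(object) {
  cat("Spectrum: MS", object@msLevel, ", ", nrow(object@peaks), " peaks",
      sep = "")
  if (!is.na(object@precursorMz))
    cat(", precursor m/z ", format(object@precursorMz, digits = 7), sep = "")
  cat("\n")
  if (nrow(object@peaks))
    cat("  m/z range ", format(min(object@peaks$mz), digits = 7), " - ",
        format(max(object@peaks$mz), digits = 7), "\n", sep = "")
})

#' Read and write MGF peak lists
#'
#' A minimal reader/writer for the Mascot generic format dialect
#' (BEGIN IONS / TITLE / PEPMASS / peak lines / END IONS).  Blocks with a
#' PEPMASS are read as MS2 spectra.
#'
#' @param path file path
#' @return \code{readMgf}: a named list of \linkS4class{Spectrum}
#'   (names taken from TITLE lines where present)
#' @export
readMgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(starts) != length(ends) || any(ends < starts))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  out <- vector("list", length(starts))
  titles <- character(length(starts))
  for (i in seq_along(starts)) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    meta <- block[kv]
    title <- sub("^TITLE=", "", grep("^TITLE=", meta, value = TRUE)[1L])
    pep <- grep("^PEPMASS=", meta, value = TRUE)
    prec <- if (length(pep))
      as.numeric(strsplit(sub("^PEPMASS=", "", pep[1L]), "[ \t]")[[1L]][1L])
    else NA_real_
    pkLines <- block[!kv & nzchar(trimws(block))]
    if (length(pkLines)) {
      m <- do.call(rbind, strsplit(trimws(pkLines), "[ \t]+"))
      mz <- as.numeric(m[, 1L])
      it <- if (ncol(m) >= 2L) as.numeric(m[, 2L]) else rep(1, length(mz))
    } else {
      mz <- numeric(); it <- numeric()
    }
    out[[i]] <- newSpectrum(mz, it, precursorMz = prec,
                            msLevel = if (is.na(prec)) 1L else 2L)
    titles[i] <- if (is.na(title)) paste0("spectrum_", i) else title
  }
  names(out) <- titles
  out
}

#' @rdname readMgf
#' @param spectra a list of \linkS4class{Spectrum} (or a single one)
#' @export
writeMgf <- function(spectra, path) {
  if (is(spectra, "Spectrum")) spectra <- list(spectra)
  if (is.null(names(spectra)))
    names(spectra) <- paste0("spectrum_", seq_along(spectra))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(spectra)) {
    s <- spectra[[nm]]
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", nm), con)
    if (!is.na(s@precursorMz))
      writeLines(paste0("PEPMASS=", format(s@precursorMz, digits = 10)), con)
    pk <- s@peaks
    if (nrow(pk))
      writeLines(paste(format(pk$mz, digits = 10, trim = TRUE),
                       format(pk$intensity, digits = 10, trim = TRUE)), con)
    writeLines("END IONS", con)
    writeLines("", con)
  }
  invisible(path)
}
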