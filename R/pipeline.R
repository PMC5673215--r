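reportHeader <- function(convention = "monoisotopic") {
  c("# orientation: patterns written non-reducing end -> reducing end",
    paste0("# mass convention: ", convention))
}

writeTsvWithHeader <- function(df, path, convention = "monoisotopic") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(reportHeader(convention), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the screening funnel on a FASTA file and write reports
#'
#' Reads a protein FASTA (and optional annotation TSV), runs
#' \code{\link{runCascade}}, and writes \code{funnel.tsv} and
#' \code{verdicts.tsv} into \code{outDir}.  Per-stage survivor counts
#' are logged to stderr.  Deterministic: identical inputs yield
#' byte-identical outputs.
#'
#' @param fastaPath protein FASTA file
#' @param annotationPath optional annotation TSV
#'   (see \code{\link{readProteinAnnotations}})
#' @param outDir output directory (created if missing)
#' @param ... passed to \code{\link{runCascade}}
#' @return the \linkS4class{ScreenReport}, invisibly
#' @export
runScreenReport <- function(fastaPath, annotationPath = NULL,
                            outDir = ".", ...) {
  if (!file.exists(fastaPath))
    stop("cannot read FASTA file: ", fastaPath)
  proteins <- readProteinCollection(fastaPath)
  if (!length(proteins))
    stop("FASTA file contains no sequences: ", fastaPath)
  annotations <- if (!is.null(annotationPath))
    readProteinAnnotations(annotationPath) else NULL
  report <- runCascade(proteins, annotations, ...)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  f <- funnel(report)
  for (k in seq_len(nrow(f)))
    message("screen: ", f$filter[k], " -> ", f$surviving[k], " proteins")
  writeTsvWithHeader(f, file.path(outDir, "funnel.tsv"))
  writeTsvWithHeader(verdicts(report), file.path(outDir, "verdicts.tsv"))
  invisible(report)
}

#' Annotate MS2 spectra from an MGF file and write reports
#'
#' For every MS2 block in the MGF file: infers the GlcNAc/GlcN
#' composition from the precursor m/z, ranks all positional isomers
#' against the fragment ladder, and runs the chain-end diagnostics.
#' A merged positional-support report pools the per-spectrum rankings
#' (spectra of the same composition weighted equally).  Writes
#' \code{pattern_scores.tsv} and \code{positional_support.json} into
#' \code{outDir}.
#'
#' @param mgfPath MGF peak-list file
#' @param dp degree of polymerization of the analyte pool; NA lists all
#'   compositions within \code{dpRange} compatible with each precursor
#' @param dpRange DP search range used when \code{dp} is NA
#' @param label reducing-end label (\code{"AMAC"})
#' @param tol m/z match tolerance
#' @param table a \linkS4class{MassTable}
#' @param outDir output directory (created if missing)
#' @return list with \code{perSpectrum} (ranked patterns and end
#'   diagnostics per spectrum), \code{compositions}, and
#'   \code{support} (merged positional support per composition),
#'   invisibly
#' @export
runMsReport <- function(mgfPath, dp = NA_integer_, dpRange = 1:12,
                        label = "AMAC", tol = 0.5, table = massTable(),
                        outDir = ".") {
  spectra <- readMgf(mgfPath)
  ms2 <- Filter(function(s) msLevel(s) == 2L, spectra)
  if (!length(ms2)) {
    warning("no MS2 blocks found in ", mgfPath, "; empty report")
    return(invisible(list(perSpectrum = list(), compositions = NULL,
                          support = list())))
  }
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  perSpectrum <- list()
  compRows <- list()
  scoreRows <- list()
  for (nm in names(ms2)) {
    s <- ms2[[nm]]
    rng <- if (is.na(dp)) dpRange else dp
    comps <- compositionFromMz(precursorMz(s), dpRange = rng,
                               label = label, table = table, tol = tol)
    compRows[[nm]] <- if (nrow(comps)) cbind(spectrum = nm, comps) else NULL
    if (!nrow(comps)) {
      message("annotate: ", nm, ": no composition within ", tol,
              " of precursor ", format(precursorMz(s)))
      next
    }
    best <- comps[1L, ]
    ranked <- rankPatterns(s, nA = best$nA, nD = best$nD, table = table,
                           tol = tol, label = label)
    ends <- endDiagnostics(s, nA = best$nA, nD = best$nD, table = table,
                           tol = tol)
    perSpectrum[[nm]] <- list(composition = best, ranked = ranked,
                              ends = ends)
    scoreRows[[nm]] <- cbind(spectrum = nm,
                             composition = sprintf("A%dD%d", best$nA,
                                                   best$nD),
                             ranked)
    message("annotate: ", nm, ": A", best$nA, "D", best$nD,
            ", top pattern ", ranked$pattern[1L])
  }
  ## pool rankings per composition: mean score per pattern across spectra
  support <- list()
  if (length(perSpectrum)) {
    comps <- vapply(perSpectrum, function(x)
      sprintf("A%dD%d", x$composition$nA, x$composition$nD), character(1L))
    for (cc in unique(comps)) {
      rk <- lapply(perSpectrum[comps == cc], `[[`, "ranked")
      pooled <- do.call(rbind, rk)
      agg <- stats::aggregate(score ~ pattern, data = pooled, FUN = mean)
      agg <- agg[order(-agg$score, agg$pattern), ]
      support[[cc]] <- positionalSupport(agg)
    }
  }
  scoreTab <- do.call(rbind, scoreRows)
  if (!is.null(scoreTab)) {
    rownames(scoreTab) <- NULL
    writeTsvWithHeader(scoreTab, file.path(outDir, "pattern_scores.tsv"),
                       table@convention)
  }
  supportJson <- lapply(support, function(x)
    list(f = as.list(x$f), ambiguity = x$ambiguity))
  jsonlite::write_json(
    list(orientation = "non-reducing end -> reducing end",
         massConvention = table@convention,
         positionalSupport = supportJson),
    file.path(outDir, "positional_support.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(perSpectrum = perSpectrum,
                 compositions = do.call(rbind, compRows),
                 support = support))
}
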