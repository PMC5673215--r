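#' Read a protein collection from FASTA
#'
#' @param path FASTA file of protein sequences
#' @return named character vector of sequences; names are the first
#'   whitespace-delimited token of each header
#' @export
readProteinCollection <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Read per-protein annotations
#'
#' Tab-separated annotation table with column \code{id} and any of
#' \code{family}, \code{complete_gene}, \code{domain_count},
#' \code{sp_start}, \code{sp_end}.  Annotation values, where present,
#' override the corresponding sequence-based heuristics in
#' \code{\link{runCascade}}.
#'
#' @param path TSV file path
#' @return data.frame keyed by \code{id}
#' @export
readProteinAnnotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (!"id" %in% names(ann)) stop("annotation table must have an 'id' column")
  ann
}

annLookup <- function(annotations, id, column) {
  if (is.null(annotations) || !column %in% names(annotations))
    return(NA)
  i <- match(id, annotations$id)
  if (is.na(i)) NA else annotations[[column]][i]
}

#' Run the CE4 candidate-selection funnel
#'
#' Applies, in order: (f0) CE4 family tag (annotation-based; proteins
#' without a family annotation pass), (f1) presence of all five CE4
#' motifs, (f2) gene completeness (annotation flag, else the sequence
#' starts with M and has no internal stop), (f3) signal peptide
#' (external call in the annotations, else the built-in heuristic),
#' (f4) single domain (annotation \code{domain_count == 1}, else mature
#' length at most \code{domainLengthThreshold}).  Because every filter
#' is a per-protein predicate, the final candidate set is the
#' intersection of the per-filter passing sets and does not depend on
#' filter order; the funnel counts do.
#'
#' @param proteins named character vector of protein sequences (see
#'   \code{\link{readProteinCollection}})
#' @param annotations optional data.frame from
#'   \code{\link{readProteinAnnotations}}
#' @param orderedMotifs require motif occurrences in order MT1 -> MT5
#' @param domainLengthThreshold mature-length proxy for single-domain
#'   proteins when no domain annotation is given (default 400 aa; CE4
#'   catalytic domains are ~200 aa, so this is permissive)
#' @param motifs motif table as from \code{\link{ce4Motifs}}
#' @return a \linkS4class{ScreenReport}
#' @name runCascade
#' @aliases funnel verdicts screenReport
#' @export
runCascade <- function(proteins, annotations = NULL, orderedMotifs = TRUE,
                       domainLengthThreshold = 400, motifs = ce4Motifs()) {
  ids <- names(proteins)
  if (is.null(ids)) ids <- sprintf("protein_%d", seq_along(proteins))
  n <- length(proteins)
  v <- data.frame(id = ids,
                  familyCE4 = logical(n), motifsPresent = logical(n),
                  complete = logical(n), signalPeptide = logical(n),
                  singleDomain = logical(n), candidate = logical(n),
                  spCleavage = rep(NA_integer_, n),
                  motifHits = rep(NA_character_, n),
                  stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    seqRaw <- proteins[[i]]
    seqNoStop <- sub("\\*$", "", seqRaw)

    fam <- annLookup(annotations, ids[i], "family")
    v$familyCE4[i] <- if (is.na(fam)) TRUE else identical(fam, "CE4")

    sc <- scanMotifs(seqNoStop, motifs = motifs, ordered = orderedMotifs)
    v$motifsPresent[i] <- sc$allPresent
    if (nrow(sc$hits))
      v$motifHits[i] <- paste(sc$hits$motifId, sc$hits$start,
                              sep = "@", collapse = ";")

    comp <- annLookup(annotations, ids[i], "complete_gene")
    v$complete[i] <- if (!is.na(comp)) as.logical(comp)
      else startsWith(seqRaw, "M") && !grepl("*", seqNoStop, fixed = TRUE)

    spEnd <- annLookup(annotations, ids[i], "sp_end")
    sp <- predictSignalPeptide(seqNoStop,
                               spEnd = if (is.na(spEnd)) NULL else spEnd)
    v$signalPeptide[i] <- sp$present
    v$spCleavage[i] <- sp$cleavagePos

    dc <- annLookup(annotations, ids[i], "domain_count")
    matureLen <- nchar(seqNoStop) -
      (if (sp$present) sp$cleavagePos else 0L)
    v$singleDomain[i] <- if (!is.na(dc)) dc == 1L
      else matureLen <= domainLengthThreshold
  }
  filters <- c("familyCE4", "motifsPresent", "complete", "signalPeptide",
               "singleDomain")
  surviving <- rep(TRUE, n)
  counts <- integer(length(filters))
  for (k in seq_along(filters)) {
    surviving <- surviving & v[[filters[k]]]
    counts[k] <- sum(surviving)
  }
  v$candidate <- surviving
  funnel <- data.frame(filter = c("input", filters),
                       surviving = c(n, counts))
  new("ScreenReport", verdicts = v, funnel = funnel)
}

#' @rdname runCascade
#' @param x a ScreenReport
#' @export
setMethod("funnel", "ScreenReport", function(x) x@funnel)

#' @rdname runCascade
#' @export
setMethod("verdicts", "ScreenReport", function(x) x@verdicts)

setMethod("show", "ScreenReport", function(object) {
  cat("ScreenReport:", nrow(object@verdicts), "proteins\n")
  f <- object@funnel
  cat("  funnel:", paste(paste0(f$filter, "=", f$surviving),
                         collapse = " -> "), "\n")
  cat("  candidates:",
      paste(object@verdicts$id[object@verdicts$candidate], collapse = ", "),
      "\n")
})
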