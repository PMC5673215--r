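## Background alphabet for synthetic proteins.  H, D, W and Y are
## reserved for the planted motif instances: every CE4 motif needs at
## least one of these four residues, so excluding them from the random
## background guarantees that motif occurrences are exactly the planted
## ones and the generator's truth labels are unambiguous.
.BG <- c("A", "C", "E", "F", "G", "I", "K", "L", "M", "N", "P", "Q",
         "R", "S", "T", "V")

## canonical planted motif instances (MT1..MT5)
.MOTIF_SEQS <- c(MT1 = "TFDD", MT2 = "HSTAH", MT3 = "RPPY",
                 MT4 = "DAADW", MT5 = "LAH")

## signal peptide engineered so the screening heuristic fires with
## cleavage exactly after residue 19: K in the n-region, a hydrophobic
## h-region, and A-S-A as the first -3/-1 small-residue site in 16-35
.SP <- "MKKRLLLALALLLFLFASA"

## N-terminus that defeats all three signal-peptide clauses: no K/R in
## 2-6 and no hydrophobic window can form from these residues
.ACIDIC <- c("E", "N", "Q", "G", "S", "P")

bgRun <- function(n, alphabet = .BG) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

## body carrying the planted motifs (in order, separated by >= 6
## background residues whose last two are never L, so no accidental
## LxH forms in front of an H-initial motif)
motifBody <- function(drop = NULL, tail = 30L) {
  keep <- setdiff(names(.MOTIF_SEQS), drop)
  parts <- character()
  starts <- integer()
  pos <- 0L
  for (id in keep) {
    spacer <- paste0(bgRun(sample(4:14, 1L)),
                     bgRun(2L, setdiff(.BG, "L")))
    parts <- c(parts, spacer)
    pos <- pos + nchar(spacer)
    starts <- c(starts, pos + 1L)
    parts <- c(parts, .MOTIF_SEQS[[id]])
    pos <- pos + nchar(.MOTIF_SEQS[[id]])
  }
  parts <- c(parts, bgRun(tail))
  names(starts) <- keep
  list(body = paste0(parts, collapse = ""), starts = starts)
}

#' Generate a synthetic protein collection with planted screening truth
#'
#' Emulates a candidate-mining input: random background sequences with
#' planted CE4 motifs, engineered signal peptides, deliberately
#' incomplete genes and over-length multi-domain decoys, in six
#' categories that by construction tile the screening funnel:
#' \enumerate{
#'   \item \code{nonCE4}: wrong family tag;
#'   \item \code{noMotifs}: CE4 tag but one of the five motifs missing;
#'   \item \code{incomplete}: all motifs, but no initial methionine or
#'     an internal stop codon;
#'   \item \code{noSignalPeptide}: complete, motifs present, acidic
#'     N-terminus with no signal peptide;
#'   \item \code{multiDomain}: signal peptide present but mature length
#'     beyond the single-domain threshold;
#'   \item \code{positive}: a single-domain secreted CE4 candidate.
#' }
#' With the default counts (16, 24, 8, 11, 4, 1) the cascade funnel is
#' 64 -> 48 -> 24 -> 16 -> 5 -> 1 by construction.
#'
#' @param counts named integer vector of per-category record counts
#' @param seed integer RNG seed; generation is bit-reproducible
#' @return list with \code{proteins} (named character vector of
#'   sequences) and \code{truth} (data.frame: id, category, family,
#'   complete_gene, sp_end, domain_count, motifStarts)
#' @examples
#' coll <- synthProteinCollection(seed = 42)
#' funnel(runCascade(coll$proteins, coll$truth[, c("id", "family")]))
#' @export
synthProteinCollection <- function(counts = c(nonCE4 = 16L, noMotifs = 24L,
                                              incomplete = 8L,
                                              noSignalPeptide = 11L,
                                              multiDomain = 4L,
                                              positive = 1L),
                                   seed = 1L) {
  need <- c("nonCE4", "noMotifs", "incomplete", "noSignalPeptide",
            "multiDomain", "positive")
  if (!all(need %in% names(counts)) || any(counts < 0))
    stop("counts must name all six categories with non-negative values")
  counts <- counts[need]
  withSeed(seed, {
    recs <- list()
    truth <- list()
    idx <- 0L
    emit <- function(seqStr, category, family, complete, spEnd, domains,
                     motifStarts) {
      idx <<- idx + 1L
      id <- sprintf("prot%03d", idx)
      recs[[id]] <<- seqStr
      truth[[id]] <<- data.frame(
        id = id, category = category, family = family,
        complete_gene = complete, sp_end = spEnd, domain_count = domains,
        motifStarts = motifStarts, stringsAsFactors = FALSE)
    }
    offsetStarts <- function(mb, offset)
      paste(names(mb$starts), mb$starts + offset, sep = "@",
            collapse = ";")

    for (i in seq_len(counts[["nonCE4"]]))
      emit(paste0("M", bgRun(280L)), "nonCE4", "GH18", TRUE, NA_integer_,
           1L, NA_character_)
    for (i in seq_len(counts[["noMotifs"]])) {
      drop <- names(.MOTIF_SEQS)[(i - 1L) %% 5L + 1L]
      mb <- motifBody(drop = drop)
      emit(paste0("M", paste0(sample(.ACIDIC, 24L, TRUE), collapse = ""),
                  mb$body),
           "noMotifs", "CE4", TRUE, NA_integer_, 1L,
           offsetStarts(mb, 25L))
    }
    for (i in seq_len(counts[["incomplete"]])) {
      mb <- motifBody()
      core <- paste0(paste0(sample(.ACIDIC, 24L, TRUE), collapse = ""),
                     mb$body)
      if (i %% 2L == 1L) {           # truncated 5' end: no initial M
        seqStr <- paste0("V", core)
      } else {                       # internal premature stop
        seqStr <- paste0("M", core, "*", bgRun(20L))
      }
      emit(seqStr, "incomplete", "CE4", FALSE, NA_integer_, 1L,
           offsetStarts(mb, 25L))
    }
    for (i in seq_len(counts[["noSignalPeptide"]])) {
      mb <- motifBody()
      emit(paste0("M", paste0(sample(.ACIDIC, 24L, TRUE), collapse = ""),
                  mb$body),
           "noSignalPeptide", "CE4", TRUE, NA_integer_, 1L,
           offsetStarts(mb, 25L))
    }
    for (i in seq_len(counts[["multiDomain"]])) {
      mb <- motifBody(tail = 420L)   # mature length far beyond 400
      emit(paste0(.SP, mb$body), "multiDomain", "CE4", TRUE, 19L, 2L,
           offsetStarts(mb, nchar(.SP)))
    }
    for (i in seq_len(counts[["positive"]])) {
      mb <- motifBody(tail = 120L)
      emit(paste0(.SP, mb$body), "positive", "CE4", TRUE, 19L, 1L,
           offsetStarts(mb, nchar(.SP)))
    }
    truthDf <- do.call(rbind, truth)
    rownames(truthDf) <- NULL
    list(proteins = unlist(recs), truth = truthDf)
  })
}

#' Write a synthetic protein collection to FASTA plus truth TSV
#'
#' @param collection list from \code{\link{synthProteinCollection}}
#' @param fastaPath,truthPath output file paths
#' @return invisibly, the two paths
#' @export
writeProteinCollection <- function(collection, fastaPath, truthPath) {
  aa <- Biostrings::AAStringSet(collection$proteins)
  Biostrings::writeXStringSet(aa, fastaPath)
  utils::write.table(collection$truth, truthPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(fastaPath, truthPath))
}
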