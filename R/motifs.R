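#' The five conserved CE4 catalytic motifs
#'
#' Carbohydrate esterase family 4 deacetylases share five short conserved
#' motifs whose residues build the catalytic machinery: MT1 T(F/Y)DD
#' (catalytic base and metal-binding aspartates), MT2 H(S/T)xxH
#' (metal-binding histidines), MT3 R(x)PY (oxyanion stabilization),
#' MT4 DxxD(W/Y) and MT5 LxH (catalytic acid histidine).  Patterns use a
#' restricted syntax: literal residues, bracketed alternative sets like
#' \code{[FY]}, and \code{x} for any residue.
#'
#' @return data.frame with columns \code{motifId} and \code{pattern}
#' @examples
#' ce4Motifs()
#' @export
ce4Motifs <- function() {
  data.frame(
    motifId = paste0("MT", 1:5),
    pattern = c("T[FY]DD", "H[ST]xxH", "RxPY", "DxxD[WY]", "LxH"))
}

#' Compile a motif pattern into a position matcher
#'
#' Restricted motif syntax: an upper-case letter matches itself, \code{x}
#' matches any residue, and \code{[...]} matches any listed residue.
#' Compilation errors report the offending offset.
#'
#' @param pattern motif string, e.g. \code{"T[FY]DD"}
#' @return a function \code{f(sequence)} returning a data.frame of all
#'   (possibly overlapping) occurrences with columns \code{start} and
#'   \code{end} (1-based, inclusive)
#' @examples
#' m <- compileMotif("H[ST]xxH")
#' m("AAHSAAHAA")
#' @export
compileMotif <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  chars <- strsplit(pattern, "")[[1L]]
  rx <- character()
  span <- 0L
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1L]
      if (is.na(j) || j == i + 1L)
        stop("malformed motif pattern at offset ", i, ": unclosed or empty []")
      set <- chars[(i + 1L):(j - 1L)]
      if (!all(set %in% LETTERS))
        stop("malformed motif pattern at offset ", i,
             ": [] may contain residue letters only")
      rx <- c(rx, paste0("[", paste0(set, collapse = ""), "]"))
      i <- j + 1L
    } else if (ch == "x") {
      rx <- c(rx, ".")
      i <- i + 1L
    } else if (ch %in% LETTERS) {
      rx <- c(rx, ch)
      i <- i + 1L
    } else {
      stop("malformed motif pattern at offset ", i, ": ", sQuote(ch))
    }
    span <- span + 1L
  }
  if (span < 3L || span > 6L)
    stop("motif length must be 3-6 residues, got ", span)
  ## lookahead makes overlapping occurrences visible
  regex <- paste0("(?=", paste0(rx, collapse = ""), ")")
  force(span)
  function(sequence) {
    hits <- gregexpr(regex, sequence, perl = TRUE)[[1L]]
    if (hits[1L] == -1L)
      return(data.frame(start = integer(), end = integer()))
    data.frame(start = as.integer(hits), end = as.integer(hits) + span - 1L)
  }
}

#' Scan a protein for the five CE4 motifs
#'
#' Finds every occurrence of each motif and decides whether all five are
#' present.  With \code{ordered = TRUE} (default) the call additionally
#' requires a non-overlapping chain of occurrences in motif order
#' MT1 -> MT5 along the sequence, matching the CE4 domain architecture;
#' the chain is built greedily (earliest occurrence starting after the
#' previous motif's end), which finds a chain whenever one exists.
#'
#' @param sequence amino-acid string (one-letter codes)
#' @param motifs data.frame as from \code{\link{ce4Motifs}}
#' @param ordered require in-order non-overlapping occurrences
#' @return list with \code{hits} (data.frame motifId, start, end over all
#'   occurrences), \code{chain} (the selected in-order occurrence per
#'   motif, or NULL), and \code{allPresent}
#' @export
scanMotifs <- function(sequence, motifs = ce4Motifs(), ordered = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  matchers <- lapply(motifs$pattern, compileMotif)
  hitList <- lapply(matchers, function(f) f(sequence))
  hits <- do.call(rbind, Map(function(id, h) {
    if (nrow(h)) cbind(motifId = id, h) else NULL
  }, motifs$motifId, hitList))
  if (is.null(hits)) hits <- data.frame(motifId = character(),
                                        start = integer(), end = integer())
  rownames(hits) <- NULL
  eachPresent <- vapply(hitList, nrow, integer(1L)) > 0L
  chain <- NULL
  if (all(eachPresent) && ordered) {
    cursor <- 0L
    sel <- vector("list", length(hitList))
    ok <- TRUE
    for (i in seq_along(hitList)) {
      h <- hitList[[i]]
      h <- h[h$start > cursor, , drop = FALSE]
      if (!nrow(h)) { ok <- FALSE; break }
      sel[[i]] <- cbind(motifId = motifs$motifId[i], h[1L, , drop = FALSE])
      cursor <- h$end[1L]
    }
    if (ok) chain <- do.call(rbind, sel)
    allPresent <- ok
  } else {
    allPresent <- all(eachPresent)
  }
  if (!is.null(chain)) rownames(chain) <- NULL
  list(hits = hits, chain = chain, allPresent = allPresent)
}
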