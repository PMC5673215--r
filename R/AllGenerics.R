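#' @rdname chosPattern
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname chosPattern
#' @export
setGeneric("chosLabel", function(x) standardGeneric("chosLabel"))

#' @rdname chosPattern
#' @export
setGeneric("dpOf", function(x) standardGeneric("dpOf"))

#' @rdname neutralMass
#' @export
setGeneric("neutralMass",
  function(pattern, table = massTable()) standardGeneric("neutralMass"))

#' @rdname neutralMass
#' @export
setGeneric("ionMz",
  function(pattern, table = massTable(), charge = 1L)
    standardGeneric("ionMz"))

#' @rdname patternStats
#' @export
setGeneric("patternStats", function(pattern) standardGeneric("patternStats"))

#' @rdname spectrum
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname spectrum
#' @export
setGeneric("precursorMz", function(x) standardGeneric("precursorMz"))

#' @rdname spectrum
#' @export
setGeneric("msLevel", function(x) standardGeneric("msLevel"))

#' @rdname screenReport
#' @export
setGeneric("funnel", function(x) standardGeneric("funnel"))

#' @rdname screenReport
#' @export
setGeneric("verdicts", function(x) standardGeneric("verdicts"))
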