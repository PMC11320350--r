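#' @rdname filterHighMissingness
#' @export
setGeneric("filterHighMissingness", function(x, threshold = 0.5, ...)
  standardGeneric("filterHighMissingness"))

#' @rdname knnImpute
#' @export
setGeneric("knnImpute", function(x, k = 10L, ...)
  standardGeneric("knnImpute"))

#' @rdname npx
#' @export
setGeneric("npx", function(x) standardGeneric("npx"))

#' @rdname npx
#' @export
setGeneric("proteinMatrix", function(x) standardGeneric("proteinMatrix"))

#' @rdname npx
#' @export
setGeneric("cohortData", function(x) standardGeneric("cohortData"))

#' @rdname npx
#' @export
setGeneric("geneMap", function(x) standardGeneric("geneMap"))

#' @rdname npx
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname scoreCohort
#' @export
setGeneric("scoreCohort", function(model, x, ...)
  standardGeneric("scoreCohort"))

#' @rdname geneSets
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname geneSets
#' @export
setGeneric("universeSize", function(x) standardGeneric("universeSize"))
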