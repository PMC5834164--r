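#' @rdname cqValues
#' @export
setGeneric("cqValues", function(x) standardGeneric("cqValues"))

#' @rdname sampleConditions
#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))

#' @rdname sampleConditions
#' @export
setGeneric("sampleReplicates", function(x) standardGeneric("sampleReplicates"))

#' @rdname geneRanks
#' @export
setGeneric("geneRanks", function(x, ...) standardGeneric("geneRanks"))

#' Per-gene statistics of a stability method
#' @rdname stabilityTable
#' @export
setGeneric("stabilityTable", function(x) standardGeneric("stabilityTable"))

#' Aggregated table of a comprehensive ranking
#' @rdname rankingTable
#' @export
setGeneric("rankingTable", function(x) standardGeneric("rankingTable"))

#' @rdname recommendedGenes
#' @export
setGeneric("recommendedGenes",
    function(x, n = 3L) standardGeneric("recommendedGenes"))

#' Summary table of a relative-expression analysis
#' @rdname expressionSummary
#' @export
setGeneric("expressionSummary",
    function(x) standardGeneric("expressionSummary"))

#' Selected candidate genes of a screen
#' @rdname selectedGenes
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' @rdname writeResultTable
#' @export
setGeneric("writeResultTable",
    function(x, path, ...) standardGeneric("writeResultTable"))
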