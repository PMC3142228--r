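#' Accessors for mirPIN classes
#'
#' @param x a mirPIN object.
#' @name accessors
NULL

#' @describeIn accessors sample conditions of a \linkS4class{PairedExpression}.
#' @export
setGeneric("sampleCondition", function(x) standardGeneric("sampleCondition"))

#' @describeIn accessors pair ids of a \linkS4class{PairedExpression}.
#' @export
setGeneric("pairId", function(x) standardGeneric("pairId"))

#' @describeIn accessors the log2 expression matrix.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @describeIn accessors features x pairs matrix of tumor - normal log2
#'   differences, pairs ordered by pair id.
#' @export
setGeneric("pairedDiffs", function(x) standardGeneric("pairedDiffs"))

#' @describeIn accessors node labels of a graph-like object.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @describeIn accessors two-column edge matrix of a graph-like object.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @describeIn accessors number of edges.
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @describeIn accessors the miRNA id of a \linkS4class{RegulatedPIN}.
#' @export
setGeneric("mirnaId", function(x) standardGeneric("mirnaId"))

#' @describeIn accessors L0 genes (DE predicted targets in the PIN).
#' @export
setGeneric("L0", function(x) standardGeneric("L0"))

#' @describeIn accessors L1 genes (interacting partners of L0).
#' @export
setGeneric("L1", function(x) standardGeneric("L1"))

#' @describeIn accessors per-feature SAM table of a \linkS4class{SamResult}.
#' @export
setGeneric("samTable", function(x) standardGeneric("samTable"))

#' @describeIn accessors convert to an \pkg{igraph} graph.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))
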