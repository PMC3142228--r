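#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' Paired tumor/normal expression matrix
#'
#' A \linkS4class{SummarizedExperiment} holding one log2-scale assay
#' (\code{"log2"}) whose columns are annotated with a \code{condition}
#' (\code{"tumor"} or \code{"normal"}) and a \code{pair_id}; every pair id
#' must occur exactly once per condition. This is the container for both the
#' miRNA and the mRNA profiles of a paired case/control design.
#'
#' @slot .  inherits all slots from \code{SummarizedExperiment}.
#' @export
setClass("PairedExpression", contains = "SummarizedExperiment")

setValidity("PairedExpression", function(object) {
  msg <- character()
  cd <- colData(object)
  if (!all(c("condition", "pair_id") %in% colnames(cd)))
    return("colData must contain 'condition' and 'pair_id'")
  cond <- as.character(cd$condition)
  pid <- as.character(cd$pair_id)
  if (!all(cond %in% c("tumor", "normal")))
    msg <- c(msg, "condition must be 'tumor' or 'normal'")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "feature ids must be unique and non-NULL")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique and non-NULL")
  if (!"log2" %in% names(SummarizedExperiment::assays(object)))
    msg <- c(msg, "assay 'log2' is required")
  tab <- table(pid, cond)
  if (length(tab) && !all(tab == 1L))
    msg <- c(msg, "every pair_id must occur exactly once per condition")
  if (length(msg)) msg else TRUE
})

#' Construct a PairedExpression object
#'
#' @param values numeric matrix (features x samples) of log2 expression with
#'   row and column names.
#' @param condition character vector, one of \code{"tumor"}/\code{"normal"}
#'   per sample.
#' @param pair_id character vector of pair identifiers per sample.
#' @return a \linkS4class{PairedExpression}.
#' @examples
#' m <- matrix(rnorm(8), 2, 4,
#'             dimnames = list(c("g1", "g2"), c("a", "b", "c", "d")))
#' pe <- PairedExpression(m, c("tumor", "normal", "tumor", "normal"),
#'                        c("p1", "p1", "p2", "p2"))
#' @export
PairedExpression <- function(values, condition, pair_id) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  se <- SummarizedExperiment(
    assays = list(log2 = values),
    colData = DataFrame(condition = as.character(condition),
                        pair_id = as.character(pair_id),
                        row.names = colnames(values)))
  new("PairedExpression", se)
}

#' Undirected protein interaction network
#'
#' A simple undirected graph over gene symbols: no self-loops, no duplicate
#' edges. Edges are stored canonically (endpoints sorted within a row, rows
#' sorted) so identical networks compare equal.
#'
#' @slot nodes character vector of gene symbols (the node universe).
#' @slot edges two-column character matrix of unordered gene pairs.
#' @export
setClass("InteractionNetwork",
         representation(nodes = "character", edges = "matrix"))

setValidity("InteractionNetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (ncol(e) != 2L) return("edges must have two columns")
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate node labels")
  if (nrow(e)) {
    if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-loops are not allowed")
    if (!all(e %in% object@nodes))
      msg <- c(msg, "edge endpoints must be members of the node set")
    key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges")
  }
  if (length(msg)) msg else TRUE
})

canonicalEdges <- function(edges) {
  edges <- as.matrix(edges)
  if (!nrow(edges)) {
    e <- matrix(character(), 0L, 2L)
    colnames(e) <- c("a", "b")
    return(e)
  }
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  e <- unique(cbind(a = a, b = b))
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

#' Construct an InteractionNetwork
#'
#' @param edges two-column character matrix or data frame of gene pairs.
#'   Self-loops are rejected; duplicates (including reversed duplicates) are
#'   collapsed.
#' @param nodes optional node universe; defaults to the genes appearing in
#'   \code{edges}. Isolated nodes may be supplied here.
#' @return an \linkS4class{InteractionNetwork}.
#' @export
InteractionNetwork <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  storage.mode(edges) <- "character"
  if (nrow(edges) && any(edges[, 1L] == edges[, 2L]))
    stop("self-loops are not allowed in an InteractionNetwork")
  e <- canonicalEdges(edges)
  if (is.null(nodes)) nodes <- sort(unique(as.vector(e)))
  new("InteractionNetwork", nodes = as.character(nodes), edges = e)
}

#' A miRNA-regulated subnetwork (L0 targets + L1 partners)
#'
#' L0 holds the miRNA's differentially expressed predicted targets present in
#' the PIN; L1 their direct interaction partners. The edge set is the PIN
#' subgraph retained for the network (induced on L0 u L1 by default).
#'
#' @slot mirna the miRNA identifier.
#' @slot L0,L1 disjoint gene sets.
#' @slot edges two-column character matrix of retained PIN edges.
#' @export
setClass("RegulatedPIN",
         representation(mirna = "character", L0 = "character",
                        L1 = "character", edges = "matrix"))

setValidity("RegulatedPIN", function(object) {
  msg <- character()
  if (length(object@mirna) != 1L) msg <- c(msg, "mirna must be length 1")
  if (length(intersect(object@L0, object@L1)))
    msg <- c(msg, "L0 and L1 must be disjoint")
  e <- object@edges
  if (ncol(e) != 2L) return("edges must have two columns")
  if (nrow(e)) {
    memb <- c(object@L0, object@L1)
    if (!all(as.vector(e) %in% memb))
      msg <- c(msg, "every edge endpoint must lie in L0 u L1")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a paired SAM analysis
#'
#' Per-feature statistics of the paired two-class Significance Analysis of
#' Microarrays: mean paired log2 difference \code{zbar}, its standard error
#' \code{s}, the regularised statistic \code{d = zbar/(s + s0)}, the fold
#' change \code{2^zbar}, the rank-matched expected statistic \code{d_exp}
#' from the sign-flip permutation null, and the call.
#'
#' @slot table data.frame with columns feature, zbar, s, d, fold_change,
#'   d_exp, call.
#' @slot s0 the fudge factor used.
#' @slot delta,fcMin the calling thresholds.
#' @slot fdr estimated permutation FDR of the calling thresholds.
#' @slot nPerm number of permutations used (all sign flips when exhaustive).
#' @slot exhaustive whether the 2^n sign flips were fully enumerated.
#' @export
setClass("SamResult",
         representation(table = "data.frame", s0 = "numeric",
                        delta = "numeric", fcMin = "numeric",
                        fdr = "numeric", nPerm = "integer",
                        exhaustive = "logical"))

setValidity("SamResult", function(object) {
  need <- c("feature", "zbar", "s", "d", "fold_change", "d_exp", "call")
  if (!all(need %in% colnames(object@table)))
    return(paste("table must contain:", paste(need, collapse = ", ")))
  if (any(object@table$s < 0)) return("s must be non-negative")
  if (object@s0 < 0) return("s0 must be non-negative")
  if (!all(object@table$call %in% c("up", "down", "unchanged")))
    return("call must be up/down/unchanged")
  TRUE
})
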