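#' @importFrom igraph graph_from_data_frame
NULL

#' @rdname accessors
#' @aliases sampleCondition,PairedExpression-method
setMethod("sampleCondition", "PairedExpression", function(x)
  as.character(colData(x)$condition))

#' @rdname accessors
setMethod("pairId", "PairedExpression", function(x)
  as.character(colData(x)$pair_id))

#' @rdname accessors
setMethod("exprValues", "PairedExpression", function(x) assay(x, "log2"))

#' @rdname accessors
setMethod("pairedDiffs", "PairedExpression", function(x) {
  cond <- sampleCondition(x)
  pid <- pairId(x)
  pairs <- sort(unique(pid))
  v <- exprValues(x)
  ti <- vapply(pairs, function(p) which(pid == p & cond == "tumor"), integer(1L))
  ni <- vapply(pairs, function(p) which(pid == p & cond == "normal"), integer(1L))
  z <- v[, ti, drop = FALSE] - v[, ni, drop = FALSE]
  colnames(z) <- pairs
  z
})

#' @rdname accessors
setMethod("networkNodes", "InteractionNetwork", function(x) x@nodes)

#' @rdname accessors
setMethod("networkEdges", "InteractionNetwork", function(x) x@edges)

#' @rdname accessors
setMethod("numEdges", "InteractionNetwork", function(x) nrow(x@edges))

#' @rdname accessors
setMethod("networkNodes", "RegulatedPIN", function(x) c(x@L0, x@L1))

#' @rdname accessors
setMethod("networkEdges", "RegulatedPIN", function(x) x@edges)

#' @rdname accessors
setMethod("numEdges", "RegulatedPIN", function(x) nrow(x@edges))

#' @rdname accessors
setMethod("mirnaId", "RegulatedPIN", function(x) x@mirna)

#' @rdname accessors
setMethod("L0", "RegulatedPIN", function(x) x@L0)

#' @rdname accessors
setMethod("L1", "RegulatedPIN", function(x) x@L1)

#' @rdname accessors
setMethod("samTable", "SamResult", function(x) x@table)

#' @rdname accessors
setMethod("asIgraph", "InteractionNetwork", function(x)
  igraph::graph_from_data_frame(
    as.data.frame(x@edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = x@nodes, stringsAsFactors = FALSE)))

#' @rdname accessors
setMethod("asIgraph", "RegulatedPIN", function(x) {
  nodes <- c(x@L0, x@L1)
  g <- igraph::graph_from_data_frame(
    as.data.frame(x@edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes,
                          layer = c(rep("L0", length(x@L0)),
                                    rep("L1", length(x@L1))),
                          stringsAsFactors = FALSE))
  g
})

setMethod("show", "PairedExpression", function(object) {
  cond <- sampleCondition(object)
  cat("PairedExpression:", nrow(object), "features x", ncol(object),
      "samples (", sum(cond == "tumor"), "tumor /",
      sum(cond == "normal"), "normal,",
      length(unique(pairId(object))), "pairs )\n")
})

setMethod("show", "InteractionNetwork", function(object) {
  cat("InteractionNetwork:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
})

setMethod("show", "RegulatedPIN", function(object) {
  cat("RegulatedPIN for", object@mirna, ": |L0| =", length(object@L0),
      ", |L1| =", length(object@L1), ",", nrow(object@edges), "edges\n")
})

setMethod("show", "SamResult", function(object) {
  tb <- table(factor(object@table$call, c("up", "down", "unchanged")))
  cat("SamResult:", nrow(object@table), "features; s0 =",
      signif(object@s0, 4), "; delta =", object@delta, "; fc >=",
      object@fcMin, "\n  calls: up", tb[["up"]], "/ down", tb[["down"]],
      "/ unchanged", tb[["unchanged"]], "; est. FDR =",
      signif(object@fdr, 4),
      if (object@exhaustive) "(exhaustive permutations)\n" else "\n")
})
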