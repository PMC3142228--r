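#' GO over-representation of a gene set
#'
#' For every term annotating at least \code{min_term} universe genes the
#' hypergeometric upper-tail probability of the overlap is computed:
#' \code{p = hypergeomTail(m, |set|, M, |universe|)} with m = annotated
#' genes in the set and M = annotated genes in the universe. Benjamini-
#' Hochberg q-values are reported across the tested terms; a term is
#' enriched iff its raw p-value passes \code{p_max}.
#'
#' @param gene_set character vector (must be a subset of \code{universe}).
#' @param go a \code{"GOAnnotation"} (propagated annotations).
#' @param universe character vector of background genes; unannotated genes
#'   still count towards the universe size.
#' @param p_max enrichment threshold on the raw p-value (default 0.001).
#' @param min_term minimum number of annotated universe genes per tested
#'   term (default 3).
#' @return data.frame: term, name, m, M, set_size, universe_size, p, q,
#'   enriched; ordered by p.
#' @export
goEnrichment <- function(gene_set, go, universe, p_max = 0.001,
                         min_term = 3L) {
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (!length(gene_set)) stop("empty gene set")
  if (!all(gene_set %in% universe))
    stop("gene_set must be a subset of the universe")
  Ms <- vapply(go$term2gene, function(g) sum(g %in% universe), integer(1L))
  test <- names(Ms)[Ms >= min_term]
  if (!length(test))
    return(data.frame(term = character(), name = character(), m = integer(),
                      M = integer(), set_size = integer(),
                      universe_size = integer(), p = numeric(), q = numeric(),
                      enriched = logical(), stringsAsFactors = FALSE))
  m <- vapply(go$term2gene[test], function(g) sum(gene_set %in% g),
              integer(1L))
  p <- hypergeomTail(m, length(gene_set), Ms[test], length(universe))
  nm <- if (is.null(go$term_name)) rep(NA_character_, length(test))
        else unname(go$term_name[test])
  out <- data.frame(term = test, name = nm, m = m, M = unname(Ms[test]),
                    set_size = length(gene_set),
                    universe_size = length(universe),
                    p = unname(p), q = stats::p.adjust(p, "BH"),
                    enriched = unname(p) <= p_max,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p, out$term), , drop = FALSE]
}

#' Coverage and term-tree metrics of an enrichment result
#'
#' Coverage is the fraction of the gene set annotated to at least one
#' enriched term. "Trees" counts the connected components of the GO-DAG
#' subgraph induced by the enriched terms (is_a edges treated as
#' undirected); alternatively (\code{trees = "top_ancestor"}) the number of
#' distinct root-most ancestors reachable from the enriched terms.
#'
#' @param gene_set the gene set that was tested.
#' @param enrichment data.frame from \code{\link{goEnrichment}}.
#' @param go the \code{"GOAnnotation"}.
#' @param trees "components" (default) or "top_ancestor".
#' @return one-row data.frame: n_enriched_terms, n_trees, coverage.
#' @export
coverageMetrics <- function(gene_set, enrichment, go,
                            trees = c("components", "top_ancestor")) {
  trees <- match.arg(trees)
  gene_set <- unique(gene_set)
  terms <- enrichment$term[enrichment$enriched]
  if (!all(terms %in% go$terms)) stop("enriched terms missing from the DAG")
  if (!length(terms))
    return(data.frame(n_enriched_terms = 0L, n_trees = 0L, coverage = 0))
  n_trees <- if (trees == "components") {
    sub <- go$dag[go$dag[, 1L] %in% terms & go$dag[, 2L] %in% terms, ,
                  drop = FALSE]
    g <- igraph::graph_from_data_frame(
      as.data.frame(sub, stringsAsFactors = FALSE), directed = FALSE,
      vertices = data.frame(name = terms, stringsAsFactors = FALSE))
    as.integer(igraph::count_components(g))
  } else {
    anc <- goAncestors(go$dag)
    roots <- setdiff(go$terms, go$dag[, 1L])   # terms with no parent
    tops <- unique(unlist(lapply(terms, function(tt) {
      a <- c(tt, anc[[tt]])
      intersect(a, roots)
    }), use.names = FALSE))
    length(tops)
  }
  n_trees <- as.integer(n_trees)
  annotated <- unique(unlist(go$term2gene[terms], use.names = FALSE))
  data.frame(n_enriched_terms = length(terms), n_trees = n_trees,
             coverage = sum(gene_set %in% annotated) / length(gene_set))
}

#' Compare L0 against L0 u L1 functionally
#'
#' Runs \code{\link{goEnrichment}} and \code{\link{coverageMetrics}} on a
#' regulated subnetwork's L0 targets alone and on the union with their L1
#' partners, producing a side-by-side coverage report.
#'
#' @param rp a \linkS4class{RegulatedPIN} (L0 must be non-empty).
#' @param go the \code{"GOAnnotation"}.
#' @param universe background gene set.
#' @param p_max,min_term see \code{\link{goEnrichment}}.
#' @return data.frame with rows "L0" and "union": gene_set, n_genes,
#'   n_enriched_terms, n_trees, coverage.
#' @export
compareLevels <- function(rp, go, universe, p_max = 0.001, min_term = 3L) {
  if (!length(L0(rp))) stop("L0 is empty")
  sets <- list(L0 = intersect(L0(rp), universe),
               union = intersect(c(L0(rp), L1(rp)), universe))
  if (!length(sets$L0)) stop("no L0 genes in the universe")
  rows <- lapply(names(sets), function(lbl) {
    enr <- goEnrichment(sets[[lbl]], go, universe, p_max, min_term)
    cm <- coverageMetrics(sets[[lbl]], enr, go)
    cbind(data.frame(gene_set = lbl, n_genes = length(sets[[lbl]]),
                     stringsAsFactors = FALSE), cm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
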