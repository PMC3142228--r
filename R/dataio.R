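## TSV dialect used throughout: tab-separated, UTF-8, '#' comment lines, no
## quoting. Parsers reject malformed input rather than repairing it.

readTsv <- function(path, ...) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
}

#' Read a paired expression matrix and its sample metadata
#'
#' The matrix file is a TSV whose first column holds feature ids and whose
#' header row holds sample ids; the metadata TSV has columns
#' \code{sample_id}, \code{condition} (tumor/normal) and \code{pair_id}.
#'
#' @param matrix_path,metadata_path file paths.
#' @return a \linkS4class{PairedExpression}.
#' @export
readExpression <- function(matrix_path, metadata_path) {
  tab <- readTsv(matrix_path)
  if (ncol(tab) < 2L) stop("expression matrix needs >= 1 sample column")
  feats <- as.character(tab[[1L]])
  if (anyDuplicated(feats)) stop("duplicate feature ids in ", matrix_path)
  vals <- tab[, -1L, drop = FALSE]
  num <- vapply(vals, is.numeric, logical(1L))
  if (!all(num))
    stop("non-numeric expression values in column(s): ",
         paste(colnames(vals)[!num], collapse = ", "))
  if (anyNA(vals)) stop("missing expression values are not supported")
  m <- as.matrix(vals)
  rownames(m) <- feats
  md <- readTsv(metadata_path)
  need <- c("sample_id", "condition", "pair_id")
  if (!all(need %in% colnames(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample ids in metadata")
  if (!setequal(colnames(m), md$sample_id))
    stop("sample ids in matrix and metadata do not match")
  md <- md[match(colnames(m), md$sample_id), ]
  pe <- PairedExpression(m, md$condition, md$pair_id)
  validObject(pe)
  pe
}

#' Write a PairedExpression to matrix + metadata TSVs
#'
#' @param x a \linkS4class{PairedExpression}.
#' @param matrix_path,metadata_path output paths.
#' @return invisibly, the two paths.
#' @export
writeExpression <- function(x, matrix_path, metadata_path) {
  m <- exprValues(x)
  # 17 significant digits so doubles survive the text round trip exactly
  fm <- apply(m, 2, function(col) formatC(col, digits = 17, format = "g"))
  df <- data.frame(feature = rownames(m), fm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  writeTsv(df, matrix_path)
  writeTsv(data.frame(sample_id = colnames(m),
                      condition = sampleCondition(x),
                      pair_id = pairId(x), stringsAsFactors = FALSE),
           metadata_path)
  invisible(c(matrix_path, metadata_path))
}

#' Read a PIN edge list
#'
#' HPRD-style two-column TSV of interacting gene symbols. Lines beginning
#' with '#' are ignored; columns beyond the second are ignored; symbols are
#' upper-cased. Self-loops are dropped (with a message); duplicate and
#' reversed-duplicate edges are collapsed.
#'
#' @param path file path.
#' @return an \linkS4class{InteractionNetwork}.
#' @export
readPIN <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(InteractionNetwork(matrix(character(), 0L, 2L)))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop("line ", idx[bad[1L]], ": expected >= 2 tab-separated fields")
  a <- toupper(vapply(fields, `[[`, character(1L), 1L))
  b <- toupper(vapply(fields, `[[`, character(1L), 2L))
  loops <- a == b
  if (any(loops))
    message("dropped ", sum(loops), " self-loop(s)")
  InteractionNetwork(cbind(a[!loops], b[!loops]))
}

#' Write a PIN edge list
#' @param net an \linkS4class{InteractionNetwork}.
#' @param path output path.
#' @export
writePIN <- function(net, path) {
  e <- networkEdges(net)
  writeLines(c("#gene_a\tgene_b", paste(e[, 1L], e[, 2L], sep = "\t")), path)
  invisible(path)
}

#' Read a miRNA -> target table
#'
#' Two-column TSV (miRNA id, gene symbol); gene symbols are upper-cased.
#'
#' @param path file path.
#' @return named list: miRNA id -> character vector of target genes.
#' @export
readTargets <- function(path) {
  df <- readTsv(path)
  if (ncol(df) < 2L) stop("target table needs two columns (miRNA, gene)")
  mir <- as.character(df[[1L]])
  gene <- toupper(as.character(df[[2L]]))
  if (any(!nzchar(gene)) || any(!nzchar(mir)))
    stop("empty miRNA or gene symbol in target table")
  tm <- split(gene, mir)
  lapply(tm, function(g) sort(unique(g)))
}

#' Write a miRNA -> target table
#' @param targets named list of target gene sets.
#' @param path output path.
#' @export
writeTargets <- function(targets, path) {
  df <- data.frame(mirna = rep(names(targets), lengths(targets)),
                   gene = unlist(targets, use.names = FALSE),
                   stringsAsFactors = FALSE)
  writeTsv(df, path)
  invisible(path)
}

topoCheckAcyclic <- function(dag) {
  if (!nrow(dag)) return(invisible(TRUE))
  terms <- unique(as.vector(dag))
  out <- split(dag[, 2L], dag[, 1L])          # child -> parents
  indeg <- stats::setNames(integer(length(terms)), terms)
  for (p in dag[, 2L]) indeg[[p]] <- indeg[[p]] + 1L
  # Kahn on reversed edges (parent depends on child is irrelevant; any
  # orientation detects a cycle)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (p in out[[v]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen != length(terms)) stop("cycle detected in GO DAG")
  invisible(TRUE)
}

goAncestors <- function(dag) {
  parents <- split(dag[, 2L], dag[, 1L])
  memo <- new.env(parent = emptyenv())
  anc <- function(tt) {
    if (!is.null(memo[[tt]])) return(memo[[tt]])
    ps <- parents[[tt]]
    res <- if (is.null(ps)) character() else
      unique(c(ps, unlist(lapply(ps, anc), use.names = FALSE)))
    memo[[tt]] <- res
    res
  }
  terms <- unique(as.vector(dag))
  stats::setNames(lapply(terms, anc), terms)
}

#' Assemble a GOAnnotation from direct annotations and a DAG
#'
#' Checks the child -> parent edge table for cycles and propagates each
#' term's gene set to all of its ancestors.
#'
#' @param annotation named list: term id -> directly annotated gene set.
#' @param dag two-column character matrix (child, parent).
#' @param term_name optional named character of human-readable term names.
#' @return list of class \code{"GOAnnotation"} with propagated
#'   \code{term2gene}, the \code{dag}, \code{term_name} and the term set.
#' @export
makeGOAnnotation <- function(annotation, dag, term_name = NULL) {
  dag <- as.matrix(dag)
  if (nrow(dag)) storage.mode(dag) <- "character"
  topoCheckAcyclic(dag)
  terms <- unique(c(names(annotation), as.vector(dag)))
  if (!all(names(annotation) %in% terms))
    stop("annotated terms missing from DAG")
  anc <- goAncestors(dag)
  t2g <- stats::setNames(vector("list", length(terms)), terms)
  for (tt in terms) t2g[[tt]] <- character()
  for (tt in names(annotation)) {
    gs <- unique(as.character(annotation[[tt]]))
    for (target in c(tt, anc[[tt]]))
      t2g[[target]] <- union(t2g[[target]], gs)
  }
  t2g <- lapply(t2g, sort)
  structure(list(term2gene = t2g, direct = annotation, dag = dag,
                 term_name = term_name, terms = terms),
            class = "GOAnnotation")
}

#' Read a GO annotation and is_a DAG
#'
#' @param annotation_path TSV with columns gene, term (optional third
#'   column: term name).
#' @param dag_path TSV with columns child, parent.
#' @return a \code{"GOAnnotation"}; annotations are propagated to ancestors
#'   on load.
#' @export
readGO <- function(annotation_path, dag_path) {
  ad <- readTsv(annotation_path)
  if (ncol(ad) < 2L) stop("annotation needs columns gene, term")
  dd <- readTsv(dag_path)
  if (ncol(dd) < 2L) stop("DAG needs columns child, parent")
  direct <- lapply(split(toupper(as.character(ad[[1L]])),
                         as.character(ad[[2L]])),
                   function(g) sort(unique(g)))
  nm <- NULL
  if (ncol(ad) >= 3L) {
    nm <- tapply(as.character(ad[[3L]]), as.character(ad[[2L]]),
                 function(x) x[[1L]])
    nm <- stats::setNames(as.character(nm), names(nm))
  }
  makeGOAnnotation(direct, as.matrix(dd[, 1:2]), term_name = nm)
}

#' Write a GOAnnotation's direct annotations and DAG
#' @param go a \code{"GOAnnotation"}.
#' @param annotation_path,dag_path output paths.
#' @export
writeGO <- function(go, annotation_path, dag_path) {
  direct <- go$direct
  df <- data.frame(gene = unlist(direct, use.names = FALSE),
                   term = rep(names(direct), lengths(direct)),
                   stringsAsFactors = FALSE)
  writeTsv(df[, c("gene", "term")], annotation_path)
  writeTsv(as.data.frame(go$dag, stringsAsFactors = FALSE), dag_path)
  invisible(c(annotation_path, dag_path))
}

#' Read a survival table
#'
#' TSV with columns subject, time (months), event (0/1) and marker.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
readSurvival <- function(path) {
  df <- readTsv(path)
  need <- c("subject", "time", "event", "marker")
  if (!all(need %in% colnames(df)))
    stop("survival table must have columns: ", paste(need, collapse = ", "))
  if (!is.numeric(df$time) || any(df$time < 0))
    stop("survival times must be non-negative numbers")
  if (!all(df$event %in% c(0L, 1L)))
    stop("event indicator must be 0 or 1")
  df
}

#' Write a survival table
#' @param surv data.frame with subject, time, event, marker.
#' @param path output path.
#' @export
writeSurvival <- function(surv, path) {
  writeTsv(surv[, c("subject", "time", "event", "marker")], path)
  invisible(path)
}

#' Export a RegulatedPIN to GraphML
#'
#' Nodes carry a \code{layer} attribute (L0/L1).
#'
#' @param rp a \linkS4class{RegulatedPIN}.
#' @param path output path.
#' @export
exportGraphML <- function(rp, path) {
  igraph::write_graph(asIgraph(rp), path, format = "graphml")
  invisible(path)
}
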