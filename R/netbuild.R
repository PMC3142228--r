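#' Build one miRNA-regulated subnetwork
#'
#' L0 is the intersection of the miRNA's predicted targets, the supplied set
#' of differentially expressed genes, and the PIN node universe. If L0 is
#' empty the network is absent (\code{NULL}). L1 collects the PIN neighbours
#' of L0 outside L0. The retained edge set is, by default, the full PIN
#' subgraph induced on L0 u L1 (including L1-L1 edges); the alternative rule
#' \code{"l0_incident"} keeps only edges touching L0.
#'
#' @param mirna miRNA identifier (must be present in \code{targets}).
#' @param de_genes character vector of genes differentially expressed in the
#'   direction being paired with the miRNA (up-regulated genes for a
#'   down-regulated miRNA).
#' @param targets named list: miRNA id -> predicted target genes.
#' @param pin an \linkS4class{InteractionNetwork}.
#' @param edge_rule "induced" (default) or "l0_incident".
#' @return a \linkS4class{RegulatedPIN}, or \code{NULL} when no DE target
#'   lies in the PIN.
#' @export
buildRegulatedPIN <- function(mirna, de_genes, targets, pin,
                              edge_rule = c("induced", "l0_incident")) {
  edge_rule <- match.arg(edge_rule)
  if (!mirna %in% names(targets)) stop("unknown miRNA id: ", mirna)
  l0 <- sort(intersect(intersect(targets[[mirna]], de_genes),
                       networkNodes(pin)))
  if (!length(l0)) return(NULL)
  e <- networkEdges(pin)
  in0a <- e[, 1L] %in% l0
  in0b <- e[, 2L] %in% l0
  touch <- in0a | in0b
  l1 <- sort(setdiff(unique(c(e[touch & !in0a, 1L], e[touch & !in0b, 2L])),
                     l0))
  keep <- if (edge_rule == "induced") {
    memb <- c(l0, l1)
    e[, 1L] %in% memb & e[, 2L] %in% memb
  } else touch
  rp <- new("RegulatedPIN", mirna = mirna, L0 = l0, L1 = l1,
            edges = e[keep, , drop = FALSE])
  validObject(rp)
  rp
}

#' Build all regulated subnetworks for a set of miRNAs
#'
#' One \linkS4class{RegulatedPIN} per miRNA with a non-empty L0, in stable
#' miRNA-id order.
#'
#' @param mirnas character vector of (e.g. down-regulated) miRNA ids.
#' @param de_genes genes differentially expressed in the paired direction
#'   (e.g. up-regulated).
#' @param targets named list: miRNA id -> predicted target genes.
#' @param pin an \linkS4class{InteractionNetwork}.
#' @param edge_rule see \code{\link{buildRegulatedPIN}}.
#' @return named list of \linkS4class{RegulatedPIN} objects.
#' @export
buildAllPINs <- function(mirnas, de_genes, targets, pin,
                         edge_rule = c("induced", "l0_incident")) {
  edge_rule <- match.arg(edge_rule)
  mirnas <- sort(intersect(mirnas, names(targets)))
  nets <- lapply(mirnas, function(m)
    buildRegulatedPIN(m, de_genes, targets, pin, edge_rule))
  names(nets) <- mirnas
  nets <- Filter(Negate(is.null), nets)
  message(length(nets), " regulated network(s) built from ",
          length(mirnas), " miRNA(s)")
  nets
}
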