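#' Robustness of activation calls to missing interactions
#'
#' Curated interactomes are incomplete; this test asks whether
#' tumor-activation calls survive random loss of interactions. For each
#' removal fraction f and each repetition, \code{floor(f * |E|)} PIN edges
#' are removed uniformly at random, each network is rebuilt from the SAME
#' differential-expression calls (its L0 gene set is fixed; edge removal
#' cannot change expression) on the reduced PIN, CePPI counts and the
#' enrichment background are recomputed on the surviving edges, and the
#' network is scored "retained" if it is still activated in tumor.
#' Per-edge correlations do not change when edges are removed, so they are
#' computed once on the full PIN.
#'
#' @param pin the full \linkS4class{InteractionNetwork}.
#' @param l0_sets named list (miRNA id -> L0 gene set) of the originally
#'   tumor-activated networks to follow.
#' @param ceppi_tumor data.frame from \code{\link{callCePPIs}} over all PIN
#'   edges in the tumor condition.
#' @param fractions removal fractions in [0, 1).
#' @param n_reps repetitions per fraction (>= 1).
#' @param alpha_act activation threshold.
#' @param edge_rule see \code{\link{buildRegulatedPIN}}.
#' @param seed integer seed for the removal draws.
#' @return list: \code{per_network} (matrix of retention fractions, network
#'   x fraction) and \code{summary} (data.frame fraction, mean_retention).
#' @export
robustnessTest <- function(pin, l0_sets, ceppi_tumor,
                           fractions = c(0.05, 0.1, 0.15, 0.2),
                           n_reps = 100L, alpha_act = 0.05,
                           edge_rule = c("induced", "l0_incident"),
                           seed = 1L) {
  edge_rule <- match.arg(edge_rule)
  if (any(fractions < 0 | fractions >= 1))
    stop("fractions must lie in [0, 1)")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (!length(l0_sets)) stop("no networks to follow")
  set.seed(as.integer(seed))

  e <- networkEdges(pin)
  m <- nrow(e)
  nodes <- networkNodes(pin)
  e1 <- match(e[, 1L], nodes)
  e2 <- match(e[, 2L], nodes)
  idx <- match(edgeKey(e[, 1L], e[, 2L]), ceppi_tumor$key)
  if (anyNA(idx)) stop("ceppi_tumor must cover every PIN edge")
  defined <- !is.na(ceppi_tumor$r)[idx]
  ceppi <- ceppi_tumor$is_ceppi[idx] & defined

  l0masks <- lapply(l0_sets, function(l0) {
    mask <- logical(length(nodes))
    mask[match(intersect(l0, nodes), nodes)] <- TRUE
    mask
  })

  ret <- matrix(0, length(l0masks), length(fractions),
                dimnames = list(names(l0_sets), paste0("f", fractions)))
  for (fi in seq_along(fractions)) {
    n_rm <- floor(fractions[fi] * m)
    for (rep in seq_len(n_reps)) {
      keep <- rep(TRUE, m)
      if (n_rm > 0L) keep[sample.int(m, n_rm)] <- FALSE
      k1 <- e1[keep]; k2 <- e2[keep]
      defk <- defined[keep]; cepk <- ceppi[keep]
      N <- sum(defk)
      K <- sum(cepk)
      for (mi in seq_along(l0masks)) {
        l0m <- l0masks[[mi]]
        in0a <- l0m[k1]; in0b <- l0m[k2]
        touch <- in0a | in0b
        inc <- if (edge_rule == "induced") {
          memb <- l0m
          memb[k2[touch & in0a]] <- TRUE
          memb[k1[touch & in0b]] <- TRUE
          memb[k1] & memb[k2]
        } else touch
        n <- sum(inc & defk)
        if (n == 0L || N == 0L) next
        k <- sum(inc & cepk)
        if (hypergeomTail(k, n, K, N) <= alpha_act)
          ret[mi, fi] <- ret[mi, fi] + 1
      }
    }
  }
  ret <- ret / n_reps
  list(per_network = ret,
       summary = data.frame(fraction = fractions,
                            mean_retention = colMeans(ret),
                            row.names = NULL))
}
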