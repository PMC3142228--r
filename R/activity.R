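edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Per-edge co-expression within one condition
#'
#' Pearson correlation of the two endpoint genes' expression profiles across
#' the samples of one condition, with a two-sided p-value from the
#' t-transform on n - 2 degrees of freedom. Edges with an endpoint missing
#' from the expression matrix are excluded (with a message); edges with a
#' zero-variance endpoint get \code{NA} correlation (they can never be
#' CePPIs).
#'
#' @param expr the mRNA \linkS4class{PairedExpression}.
#' @param edges two-column character matrix of gene pairs (e.g.
#'   \code{networkEdges(pin)}).
#' @param condition "tumor" or "normal".
#' @return data.frame with columns a, b, key, r, p.
#' @export
edgeCoexpression <- function(expr, edges, condition = c("tumor", "normal")) {
  condition <- match.arg(condition)
  cols <- which(sampleCondition(expr) == condition)
  if (length(cols) < 3L) stop("need >= 3 samples in condition ", condition)
  v <- exprValues(expr)[, cols, drop = FALSE]
  edges <- as.matrix(edges)
  present <- edges[, 1L] %in% rownames(v) & edges[, 2L] %in% rownames(v)
  if (any(!present))
    message("excluded ", sum(!present),
            " edge(s) with endpoints absent from the expression matrix")
  e <- edges[present, , drop = FALSE]
  if (!nrow(e))
    return(data.frame(a = character(), b = character(), key = character(),
                      r = numeric(), p = numeric(),
                      stringsAsFactors = FALSE))
  A <- v[e[, 1L], , drop = FALSE]
  B <- v[e[, 2L], , drop = FALSE]
  Ac <- A - rowMeans(A)
  Bc <- B - rowMeans(B)
  sa <- rowSums(Ac^2)
  sb <- rowSums(Bc^2)
  r <- rowSums(Ac * Bc) / sqrt(sa * sb)
  r[sa == 0 | sb == 0] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  n <- length(cols)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[!is.na(r) & abs(r) == 1] <- 0
  data.frame(a = e[, 1L], b = e[, 2L], key = edgeKey(e[, 1L], e[, 2L]),
             r = r, p = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag co-expressed PPIs (CePPIs)
#'
#' An edge is a CePPI in a condition iff its correlation passes
#' \code{r_min} (either requiring a positive correlation or comparing
#' \code{|r|}) and its p-value passes \code{alpha}. Undefined correlations
#' are never CePPIs.
#'
#' @param coexp a data.frame from \code{\link{edgeCoexpression}}.
#' @param r_min correlation threshold in [0, 1].
#' @param alpha p-value threshold in (0, 1].
#' @param sign "positive" (default; r >= r_min) or "absolute"
#'   (|r| >= r_min).
#' @return the input with an added logical column \code{is_ceppi}.
#' @export
callCePPIs <- function(coexp, r_min = 0.5, alpha = 0.05,
                       sign = c("positive", "absolute")) {
  sign <- match.arg(sign)
  if (r_min < 0) stop("r_min must be non-negative")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  rr <- if (sign == "positive") coexp$r else abs(coexp$r)
  flag <- !is.na(coexp$r) & rr >= r_min & coexp$p <= alpha
  coexp$is_ceppi <- flag
  coexp
}

#' Upper-tail hypergeometric probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim Hypergeom(N, K, n)}: drawing n items
#' from a population of N containing K successes.
#'
#' @param k observed successes in the draw.
#' @param n draw size.
#' @param K successes in the population.
#' @param N population size.
#' @return the exact upper-tail probability.
#' @export
hypergeomTail <- function(k, n, K, N) {
  if (any(k < 0 | n < k | N < n | K < k | N < K))
    stop("require 0 <= k <= n <= N and k <= K <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value obtained by summing, over all tables with the
#' observed margins, the probabilities of those no more likely than the
#' observed table.
#'
#' @param tab 2x2 matrix of non-negative integer counts (not all zero).
#' @return the two-sided p-value.
#' @export
fisher2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (sum(tab) == 0) stop("all-zero table")
  stats::fisher.test(tab)$p.value
}

#' Condition-specific activity of one regulated subnetwork
#'
#' Per condition the network's CePPI count is tested for enrichment against
#' the background of all PIN edges with a defined correlation:
#' \code{p = hypergeomTail(k, n, K, N)} with k = network CePPIs, n = network
#' edges (with defined correlation), K = background CePPIs, N = background
#' edges. A condition is "activated" iff p <= alpha_act; the label combines
#' the two conditions.
#'
#' @param rp a \linkS4class{RegulatedPIN}.
#' @param ceppi list with elements \code{tumor} and \code{normal}, each a
#'   data.frame from \code{\link{callCePPIs}} over the background PIN edges.
#' @param alpha_act activation threshold (default 0.05).
#' @return one-row data.frame: mirna, n_edges, and per condition k, n, K,
#'   N, p, plus the four-way \code{label}.
#' @export
networkActivity <- function(rp, ceppi, alpha_act = 0.05) {
  stopifnot(is(rp, "RegulatedPIN"), all(c("tumor", "normal") %in% names(ceppi)))
  e <- networkEdges(rp)
  keys <- if (nrow(e)) edgeKey(e[, 1L], e[, 2L]) else character()
  one <- function(cond) {
    bg <- ceppi[[cond]]
    defined <- !is.na(bg$r)
    N <- sum(defined)
    K <- sum(bg$is_ceppi)
    idx <- match(keys, bg$key)
    if (anyNA(idx) && length(keys))
      stop("network edges must be a subset of the background edges")
    inN <- defined[idx]
    n <- sum(inN)
    k <- if (n) sum(bg$is_ceppi[idx][inN]) else 0L
    p <- if (n == 0L) 1.0 else hypergeomTail(k, n, K, N)
    list(k = k, n = n, K = K, N = N, p = p, act = n > 0L && p <= alpha_act)
  }
  tu <- one("tumor")
  no <- one("normal")
  label <- if (tu$act && no$act) "activated_both"
           else if (tu$act) "activated_tumor"
           else if (no$act) "activated_normal"
           else "inactive_both"
  if (nrow(e) == 0L) {
    label <- "inactive_both"
    message("network for ", mirnaId(rp), " has no edges; inactive by definition")
  }
  data.frame(mirna = mirnaId(rp), n_edges = nrow(e),
             k_tumor = tu$k, n_tumor = tu$n, K_tumor = tu$K, N_tumor = tu$N,
             p_tumor = tu$p,
             k_normal = no$k, n_normal = no$n, K_normal = no$K,
             N_normal = no$N, p_normal = no$p,
             label = label, stringsAsFactors = FALSE)
}

#' Activity table for a list of regulated subnetworks
#'
#' @param nets named list of \linkS4class{RegulatedPIN}.
#' @param ceppi as in \code{\link{networkActivity}}.
#' @param alpha_act activation threshold.
#' @param adjust optional multiple-testing adjustment ("none" or "BH")
#'   applied per condition across networks before labelling.
#' @return data.frame with one row per network.
#' @export
activityTable <- function(nets, ceppi, alpha_act = 0.05,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!length(nets))
    return(data.frame(mirna = character(), label = character(),
                      stringsAsFactors = FALSE))
  rows <- do.call(rbind, lapply(nets, networkActivity, ceppi = ceppi,
                                alpha_act = alpha_act))
  rownames(rows) <- NULL
  if (adjust == "BH") {
    qt <- stats::p.adjust(rows$p_tumor, "BH")
    qn <- stats::p.adjust(rows$p_normal, "BH")
    at <- rows$n_tumor > 0 & qt <= alpha_act
    an <- rows$n_normal > 0 & qn <= alpha_act
    rows$label <- ifelse(at & an, "activated_both",
                  ifelse(at, "activated_tumor",
                  ifelse(an, "activated_normal", "inactive_both")))
  }
  rows
}
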