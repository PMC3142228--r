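# Shared fixture builders. Everything is generated in code; no files.

# Paired expression object from a features x (2 * n_pairs) matrix whose
# columns alternate tumor/normal within each pair.
makePairedExpr <- function(values, n_pairs = ncol(values) / 2) {
  pairs <- sprintf("P%02d", seq_len(n_pairs))
  colnames(values) <- as.vector(rbind(paste0(pairs, "T"), paste0(pairs, "N")))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%03d", seq_len(nrow(values)))
  PairedExpression(values, rep(c("tumor", "normal"), n_pairs),
                   rep(pairs, each = 2))
}

# Random paired matrix with optional per-feature tumor shifts.
randomPairedExpr <- function(n_feat, n_pairs, shift = 0, sd = 0.5,
                             seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n_feat * 2 * n_pairs, 8, 1), n_feat, 2 * n_pairs)
  tum <- seq(1, 2 * n_pairs, by = 2)
  x[, tum] <- x[, tum] + shift
  x <- x + matrix(rnorm(length(x), 0, sd), nrow(x))
  makePairedExpr(x, n_pairs)
}

# Random simple undirected graph over `genes`, ~p edge probability.
randomPin <- function(genes, p = 0.1, seed = 1) {
  set.seed(seed)
  cmb <- t(combn(genes, 2))
  keep <- runif(nrow(cmb)) < p
  InteractionNetwork(cmb[keep, , drop = FALSE], nodes = genes)
}

# Brute-force regulated-network construction used as netbuild oracle.
bruteRegulated <- function(l0, pin_edges, edge_rule = "induced") {
  l0 <- sort(l0)
  nb <- character()
  for (i in seq_len(nrow(pin_edges))) {
    a <- pin_edges[i, 1]; b <- pin_edges[i, 2]
    if (a %in% l0 && !(b %in% l0)) nb <- c(nb, b)
    if (b %in% l0 && !(a %in% l0)) nb <- c(nb, a)
  }
  l1 <- sort(unique(nb))
  memb <- c(l0, l1)
  keep <- logical(nrow(pin_edges))
  for (i in seq_len(nrow(pin_edges))) {
    a <- pin_edges[i, 1]; b <- pin_edges[i, 2]
    keep[i] <- if (edge_rule == "induced") a %in% memb && b %in% memb
               else a %in% l0 || b %in% l0
  }
  list(L0 = l0, L1 = l1, edges = pin_edges[keep, , drop = FALSE])
}

# Exact upper-tail hypergeometric by log-space summation of the closed-form
# pmf (independent of stats::phyper).
oracleHyperTail <- function(k, n, K, N) {
  j <- seq(k, min(n, K))
  if (!length(j)) return(0)
  lp <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  sum(exp(lp))
}

# Two-sided Fisher p by enumeration over all tables with the observed
# margins; tables no more probable than the observed one (with the usual
# relative tolerance for floating-point ties) are summed.
oracleFisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, c1 - (n - r1)):min(r1, c1)
  lp <- lchoose(r1, a_range) + lchoose(n - r1, c1 - a_range) - lchoose(n, c1)
  p <- exp(lp)
  obs <- p[a_range == tab[1, 1]]
  sum(p[p <= obs * (1 + 1e-7)])
}

# Toy GO: root T1 with children T2, T3; T2 has children T4, T5.
toyGO <- function() {
  dag <- rbind(c("T2", "T1"), c("T3", "T1"), c("T4", "T2"), c("T5", "T2"))
  colnames(dag) <- c("child", "parent")
  ann <- list(T3 = c("G1", "G2", "G3"), T4 = c("G4", "G5"),
              T5 = c("G5", "G6"))
  makeGOAnnotation(ann, dag)
}

# Independent oracle: per-feature paired SAM statistics from first
# principles, kept deliberately naive (explicit loops).
oracleSamStats <- function(z, s0) {
  t(apply(z, 1, function(zk) {
    n <- length(zk)
    zb <- sum(zk) / n
    s <- sqrt(sum((zk - zb)^2) / (n * (n - 1)))
    c(zbar = zb, s = s, d = zb / (s + s0), fc = 2^zb)
  }))
}

# Brute-force oracle for the full SAM calling procedure: enumerate all 2^n
# sign flips explicitly and apply the rank-matched delta + fold-change rule.
oracleSamCall <- function(z, s0, delta, fc_min) {
  n <- ncol(z); p <- nrow(z)
  stats <- oracleSamStats(z, s0)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  dmat <- matrix(NA_real_, p, nrow(signs))
  for (b in seq_len(nrow(signs))) {
    zp <- sweep(z, 2, signs[b, ], "*")
    dmat[, b] <- oracleSamStats(zp, s0)[, "d"]
  }
  d_exp <- rowMeans(apply(dmat, 2, sort))
  ord <- order(stats[, "d"])
  diff <- numeric(p)
  diff[ord] <- stats[ord, "d"] - d_exp
  unname(ifelse(diff >= delta & stats[, "fc"] >= fc_min, "up",
                ifelse(diff <= -delta & stats[, "fc"] <= 1 / fc_min, "down",
                       "unchanged")))
}
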