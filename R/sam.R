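#' Paired SAM statistics
#'
#' For each feature, the paired two-class Significance Analysis of
#' Microarrays statistic: with per-pair log2 differences
#' \eqn{z_k = tumor_k - normal_k},
#' \deqn{\bar z = mean(z), \quad s = \sqrt{\sum_k (z_k - \bar z)^2 / (n(n-1))},
#'  \quad d = \bar z / (s + s_0), \quad fold\_change = 2^{\bar z}.}
#'
#' @param expr a \linkS4class{PairedExpression} (>= 3 pairs).
#' @param s0 non-negative fudge factor; \code{NULL} (default) selects it via
#'   \code{\link{chooseS0}}.
#' @return data.frame with columns feature, zbar, s, d, fold_change; the
#'   chosen s0 is attached as attribute \code{"s0"}.
#' @export
samStatistics <- function(expr, s0 = NULL) {
  z <- pairedDiffs(expr)
  n <- ncol(z)
  if (n < 3L) stop("paired SAM requires at least 3 sample pairs")
  zbar <- rowMeans(z)
  s <- sqrt(rowSums((z - zbar)^2) / (n * (n - 1)))
  if (is.null(s0)) s0 <- chooseS0(zbar, s)
  if (s0 < 0) stop("s0 must be non-negative")
  data.frame(feature = rownames(z), zbar = zbar, s = s,
             d = zbar / (s + s0), fold_change = 2^zbar,
             row.names = NULL, stringsAsFactors = FALSE) ->
    out
  attr(out, "s0") <- s0
  out
}

#' Choose the SAM fudge factor s0
#'
#' Tusher-style selection: candidate values are the percentiles
#' \{0, 5, ..., 100\} of the per-feature standard errors s. For each
#' candidate the features are partitioned into 100 s-quantile windows and
#' the coefficient of variation of the windows' median absolute d deviations
#' is computed; the candidate minimising the CV wins, ties going to the
#' smallest percentile. With fewer than 20 features the procedure is
#' unstable and the fallback s0 = median(s) is used (with a message).
#'
#' @param zbar,s per-feature mean paired differences and standard errors.
#' @return the chosen s0.
#' @export
chooseS0 <- function(zbar, s) {
  p <- length(s)
  stopifnot(length(zbar) == p)
  if (p < 20L) {
    message("fewer than 20 features; falling back to s0 = median(s)")
    return(stats::median(s))
  }
  cands <- stats::quantile(s, seq(0, 1, 0.05), names = FALSE, type = 7)
  breaks <- unique(stats::quantile(s, seq(0, 1, 0.01), names = FALSE))
  win <- if (length(breaks) > 1L)
    cut(s, breaks, include.lowest = TRUE) else factor(rep(1L, p))
  cv <- vapply(cands, function(a) {
    d <- zbar / (s + a)
    v <- tapply(d, win, function(x) stats::median(abs(x - stats::median(x))))
    v <- v[!is.na(v)]
    if (length(v) < 2L || mean(v) == 0) return(0)
    stats::sd(v) / mean(v)
  }, numeric(1L))
  cands[which.min(cv)]
}

signMatrix <- function(n, n_perm) {
  if (2^n <= n_perm) {
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    list(S = t(S), exhaustive = TRUE)
  } else {
    list(S = matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm),
         exhaustive = FALSE)
  }
}

#' Call differentially expressed features with paired SAM
#'
#' The permutation null is formed by random sign flips of each pair's
#' difference vector (all \eqn{2^n} flips are enumerated when
#' \eqn{2^n \le n\_perm}, otherwise \code{n_perm} are sampled). The expected
#' statistic at rank i, \eqn{\bar d_{exp}(i)}, is the mean over permutations
#' of the i-th order statistic of the permuted d. A feature is called up if
#' \eqn{d - \bar d_{exp} \ge \delta} and \eqn{fold\_change \ge fc\_min},
#' down if \eqn{d - \bar d_{exp} \le -\delta} and
#' \eqn{fold\_change \le 1/fc\_min}. The reported FDR is the median across
#' permutations of the number of permuted features passing the same
#' rank-matched thresholds, divided by the number of features called (1.0
#' when nothing is called).
#'
#' @param expr a \linkS4class{PairedExpression}.
#' @param delta non-negative calling threshold on \eqn{d - \bar d_{exp}}.
#' @param fc_min fold-change threshold (>= 1).
#' @param n_perm number of permutations (>= 1).
#' @param s0 optional fudge factor; selected by \code{\link{chooseS0}} when
#'   \code{NULL}.
#' @param seed optional integer seed for the sampled sign flips.
#' @return a \linkS4class{SamResult}.
#' @export
samCall <- function(expr, delta = 5, fc_min = 2, n_perm = 1000L,
                    s0 = NULL, seed = NULL) {
  if (delta < 0) stop("delta must be >= 0")
  if (fc_min < 1) stop("fc_min must be >= 1")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  st <- samStatistics(expr, s0 = s0)
  s0 <- attr(st, "s0")
  z <- pairedDiffs(expr)
  n <- ncol(z)
  p <- nrow(z)

  sm <- signMatrix(n, n_perm)
  B <- ncol(sm$S)
  ## permuted means: (z %*% S)/n ; permuted sums of squares are unchanged by
  ## sign flips, so s* derives from rowSums(z^2) and the permuted mean alone.
  M <- (z %*% sm$S) / n
  ssq <- rowSums(z^2)
  sp <- sqrt(pmax(ssq - n * M^2, 0) / (n * (n - 1)))
  dperm <- M / (sp + s0)

  ord_perm <- apply(dperm, 2L, order)
  d_sorted <- matrix(dperm[cbind(as.vector(ord_perm),
                                 rep(seq_len(B), each = p))], p, B)
  d_exp <- rowMeans(d_sorted)

  ord <- order(st$d)
  d_exp_feat <- numeric(p)
  d_exp_feat[ord] <- d_exp            # expected statistic at each feature's rank
  diff_obs <- st$d - d_exp_feat
  up <- diff_obs >= delta & st$fold_change >= fc_min
  down <- diff_obs <= -delta & st$fold_change <= 1 / fc_min
  call <- ifelse(up, "up", ifelse(down, "down", "unchanged"))
  n_called <- sum(up) + sum(down)

  fc_perm <- matrix(2^M[cbind(as.vector(ord_perm),
                              rep(seq_len(B), each = p))], p, B)
  exceed <- colSums((d_sorted - d_exp >= delta & fc_perm >= fc_min) |
                    (d_sorted - d_exp <= -delta & fc_perm <= 1 / fc_min))
  fdr <- if (n_called == 0L) 1.0 else
    min(1.0, stats::median(exceed) / n_called)

  tab <- data.frame(feature = st$feature, zbar = st$zbar, s = st$s,
                    d = st$d, fold_change = st$fold_change,
                    d_exp = d_exp_feat, call = call,
                    stringsAsFactors = FALSE)
  new("SamResult", table = tab, s0 = s0, delta = delta, fcMin = fc_min,
      fdr = fdr, nPerm = B, exhaustive = sm$exhaustive)
}

#' Features called in a given direction
#'
#' @param x a \linkS4class{SamResult}.
#' @param direction "up" or "down".
#' @return character vector of feature ids.
#' @export
calledFeatures <- function(x, direction = c("up", "down")) {
  direction <- match.arg(direction)
  tb <- samTable(x)
  tb$feature[tb$call == direction]
}
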