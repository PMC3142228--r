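#' ROC AUC of a marker for tumor/normal discrimination
#'
#' The AUC is computed from the Mann-Whitney U statistic with half credit
#' for ties. For a down-regulated marker the natural orientation is
#' \code{direction = "lower"}: the AUC is the probability that a tumor
#' sample scores lower than a normal sample. The p-value uses the
#' large-sample normal approximation of the rank-sum statistic with tie
#' correction (two-sided).
#'
#' @param values numeric marker values.
#' @param labels logical or 0/1 vector; TRUE/1 = tumor (positive class).
#' @param direction "lower" (default): tumor expected lower; "higher":
#'   tumor expected higher.
#' @return data.frame: auc, p, n_pos, n_neg.
#' @export
rocAUC <- function(values, labels, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (anyNA(values) || anyNA(labels)) stop("missing values not supported")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("need at least one of each class")
  rk <- rank(values)                      # midranks handle ties
  U_higher <- sum(rk[labels]) - n_pos * (n_pos + 1) / 2
  U <- if (direction == "higher") U_higher else n_pos * n_neg - U_higher
  auc <- U / (n_pos * n_neg)
  n <- n_pos + n_neg
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  varU <- n_pos * n_neg / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- if (varU > 0) (U - n_pos * n_neg / 2) / sqrt(varU) else 0
  data.frame(auc = auc, p = 2 * stats::pnorm(-abs(z)),
             n_pos = n_pos, n_neg = n_neg)
}

#' Combined multi-marker score and its AUC
#'
#' Each marker is z-scored over all samples and sign-oriented so that larger
#' values are more tumor-like; the per-sample mean of the oriented z-scores
#' is the combined score. Reports the AUC of the combined score
#' (\code{direction = "higher"}) together with the overall correct
#' classification: accuracy at the Youden-optimal ROC threshold.
#'
#' @param panel numeric matrix, markers x samples (>= 2 markers).
#' @param labels logical or 0/1 vector; TRUE/1 = tumor.
#' @return data.frame: auc, p, accuracy, n_markers, n_pos, n_neg.
#' @export
combinedScore <- function(panel, labels) {
  panel <- as.matrix(panel)
  labels <- as.logical(labels)
  if (nrow(panel) < 2L) stop("need at least 2 markers")
  sds <- apply(panel, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant marker(s)")
    panel <- panel[sds > 0, , drop = FALSE]
    if (nrow(panel) < 1L) stop("no informative markers left")
  }
  zs <- t(scale(t(panel)))
  orient <- sign(rowMeans(zs[, labels, drop = FALSE]) -
                 rowMeans(zs[, !labels, drop = FALSE]))
  orient[orient == 0] <- 1
  score <- colMeans(zs * orient)
  roc <- rocAUC(score, labels, direction = "higher")
  thr <- sort(unique(score))
  cuts <- c(-Inf, (thr[-1] + thr[-length(thr)]) / 2, Inf)
  youden <- vapply(cuts, function(ct) {
    sens <- sum(score >= ct & labels) / sum(labels)
    spec <- sum(score < ct & !labels) / sum(!labels)
    sens + spec - 1
  }, numeric(1L))
  best <- cuts[which.max(youden)]
  acc <- mean((score >= best) == labels)
  data.frame(auc = roc$auc, p = roc$p, accuracy = acc,
             n_markers = nrow(panel), n_pos = roc$n_pos, n_neg = roc$n_neg)
}

#' Median split of marker values
#'
#' Values at or above the median go to the "high" group, strictly below to
#' "low" (ties to high). If all values are identical everyone is "high" and
#' a warning is raised.
#'
#' @param values numeric vector (length >= 2).
#' @return factor with levels "high"/"low".
#' @export
medianSplit <- function(values) {
  if (length(values) < 2L) stop("need at least 2 subjects")
  med <- stats::median(values)
  grp <- ifelse(values >= med, "high", "low")
  if (all(grp == "high")) warning("all values identical; everyone is 'high'")
  factor(grp, levels = c("high", "low"))
}

#' Kaplan-Meier estimator
#'
#' Product-limit estimate of the survival function over the distinct event
#' times, via \code{survival::survfit}. With censored-only data S(t) = 1
#' everywhere.
#'
#' @param surv data.frame with columns time and event (0/1).
#' @return data.frame: time, n_risk, n_event, survival; a virtual first row
#'   at t = 0 with S = 1 is included.
#' @export
kmEstimator <- function(surv) {
  if (!nrow(surv)) stop("need at least 1 subject")
  if (any(surv$time < 0)) stop("negative survival time")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = surv)
  data.frame(time = c(0, fit$time),
             n_risk = c(nrow(surv), fit$n.risk),
             n_event = c(0, fit$n.event),
             survival = c(1, fit$surv))
}

kmStep <- function(km) stats::stepfun(km$time[-1L], km$survival, right = FALSE)

#' Maximum difference in survival rates (Dmax)
#'
#' Both groups' Kaplan-Meier curves are evaluated on the union of their
#' event times; Dmax is the largest absolute difference
#' \eqn{max_t |S_{high}(t) - S_{low}(t)|}, achieved at an event time since
#' the curves are step functions.
#'
#' @param group_high,group_low survival data.frames (time, event).
#' @return data.frame: dmax, time.
#' @export
dmaxStat <- function(group_high, group_low) {
  if (!nrow(group_high) || !nrow(group_low)) stop("both groups must be non-empty")
  km_h <- kmEstimator(group_high)
  km_l <- kmEstimator(group_low)
  ev <- sort(unique(c(group_high$time[group_high$event == 1],
                      group_low$time[group_low$event == 1])))
  if (!length(ev)) return(data.frame(dmax = 0, time = NA_real_))
  dh <- kmStep(km_h)(ev)
  dl <- kmStep(km_l)(ev)
  dd <- abs(dh - dl)
  i <- which.max(dd)
  data.frame(dmax = dd[i], time = ev[i])
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank statistic over the pooled event
#' times, via \code{survival::survdiff}.
#'
#' @param group_a,group_b survival data.frames (time, event).
#' @return data.frame: chi2, p.
#' @export
logrankTest <- function(group_a, group_b) {
  df <- rbind(data.frame(time = group_a$time, event = group_a$event,
                         g = "a", stringsAsFactors = FALSE),
              data.frame(time = group_b$time, event = group_b$event,
                         g = "b", stringsAsFactors = FALSE))
  if (sum(df$event) == 0) stop("log-rank test needs at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  data.frame(chi2 = unname(sd$chisq),
             p = stats::pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE))
}

#' Marker evaluation table
#'
#' Per-marker ROC/AUC on tumor-vs-normal expression, plus a combined-panel
#' row, and (when survival data are supplied) a median-split survival
#' analysis of the marker values: Kaplan-Meier log-rank p and Dmax.
#'
#' @param expr a \linkS4class{PairedExpression} (e.g. the miRNA matrix).
#' @param markers character vector of feature ids to evaluate (e.g. the
#'   called down-regulated miRNAs).
#' @param direction per-marker ROC orientation (see \code{\link{rocAUC}}).
#' @param surv optional survival data.frame with columns time, event,
#'   marker; the median split is on the marker column.
#' @return list: \code{per_marker} data.frame (marker, auc, p),
#'   \code{combined} data.frame (or NULL if < 2 markers), and
#'   \code{survival} data.frame (logrank chi2/p, dmax, dmax_time) or NULL.
#' @export
markerTable <- function(expr, markers, direction = "lower", surv = NULL) {
  v <- exprValues(expr)
  markers <- intersect(markers, rownames(v))
  labels <- sampleCondition(expr) == "tumor"
  per <- NULL
  if (length(markers)) {
    per <- do.call(rbind, lapply(markers, function(m)
      cbind(data.frame(marker = m, stringsAsFactors = FALSE),
            rocAUC(v[m, ], labels, direction))))
    rownames(per) <- NULL
  }
  combined <- if (length(markers) >= 2L)
    combinedScore(v[markers, , drop = FALSE], labels) else NULL
  sv <- NULL
  if (!is.null(surv)) {
    grp <- medianSplit(surv$marker)
    hi <- surv[grp == "high", ]
    lo <- surv[grp == "low", ]
    if (nrow(hi) && nrow(lo) && sum(surv$event) > 0) {
      lr <- logrankTest(hi, lo)
      dm <- dmaxStat(hi, lo)
      sv <- data.frame(n_high = nrow(hi), n_low = nrow(lo),
                       logrank_chi2 = lr$chi2, logrank_p = lr$p,
                       dmax = dm$dmax, dmax_time = dm$time)
    }
  }
  list(per_marker = per, combined = combined, survival = sv)
}
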