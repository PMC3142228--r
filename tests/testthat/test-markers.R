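test_that("AUC equals the all-pairs counting oracle", {
  oracleAUC <- function(v, lab, lower = TRUE) {
    pos <- v[lab]; neg <- v[!lab]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + if (lower) (p < q) + 0.5 * (p == q)
                   else (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(5)
  for (rep in 1:10) {
    v <- round(rnorm(10), 1)              # rounding forces occasional ties
    lab <- rep(c(TRUE, FALSE), each = 5)
    expect_equal(rocAUC(v, lab, "lower")$auc, oracleAUC(v, lab, TRUE))
    expect_equal(rocAUC(v, lab, "higher")$auc, oracleAUC(v, lab, FALSE))
    # label swap maps auc -> 1 - auc (up to tie symmetry)
    expect_equal(rocAUC(v, !lab, "lower")$auc,
                 1 - rocAUC(v, lab, "lower")$auc)
    # invariance under strictly monotone transforms
    expect_equal(rocAUC(exp(v), lab, "lower")$auc,
                 rocAUC(v, lab, "lower")$auc)
  }
  # perfect separation and all-tie baselines
  expect_equal(rocAUC(c(1, 2, 3, 7, 8, 9),
                      c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                      "lower")$auc, 1.0)
  expect_equal(rocAUC(rep(1, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  expect_error(rocAUC(1:3, c(TRUE, TRUE, TRUE)), "each class")
})

test_that("AUC p-values agree with the tie-corrected rank-sum test", {
  set.seed(9)
  v <- round(rnorm(20), 1)
  lab <- rep(c(TRUE, FALSE), 10)
  p <- rocAUC(v, lab)$p
  ref <- wilcox.test(v[lab], v[!lab], exact = FALSE, correct = FALSE)$p.value
  expect_equal(p, ref, tolerance = 1e-10)
})

test_that("combined score behaves like an averaged panel", {
  set.seed(4)
  lab <- rep(c(TRUE, FALSE), each = 11)
  base <- rnorm(22) + ifelse(lab, 1, 0)
  panel <- rbind(base, base)              # identical duplicated marker
  cs <- combinedScore(panel, lab)
  expect_equal(cs$auc, rocAUC(base, lab, "higher")$auc)

  # two perfectly separating markers classify perfectly
  m1 <- ifelse(lab, 2, 0) + runif(22, 0, 0.5)
  m2 <- ifelse(lab, -2, 0) + runif(22, 0, 0.5)   # opposite orientation
  cs2 <- combinedScore(rbind(m1, m2), lab)
  expect_equal(cs2$accuracy, 1.0)
  expect_equal(cs2$auc, 1.0)

  expect_warning(combinedScore(rbind(m1, rep(1, 22)), lab), "constant")
  expect_error(combinedScore(rbind(m1), lab), "2 markers")
})

test_that("averaging independent informative markers rarely hurts", {
  wins <- vapply(1:50, function(seed) {
    set.seed(seed)
    lab <- rep(c(TRUE, FALSE), each = 11)
    panel <- t(sapply(1:4, function(i) rnorm(22) + ifelse(lab, 1, 0)))
    single <- max(apply(panel, 1, function(v)
      rocAUC(v, lab, "higher")$auc))
    combinedScore(panel, lab)$auc >= single
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("median split sends ties to the high group", {
  expect_identical(as.character(medianSplit(1:4)),
                   c("low", "low", "high", "high"))
  grp <- medianSplit(c(1, 2, 2, 3))       # median 2; ties go high
  expect_identical(as.character(grp), c("low", "high", "high", "high"))
  expect_warning(g <- medianSplit(rep(3, 4)), "identical")
  expect_true(all(g == "high"))
  expect_error(medianSplit(1), "2 subjects")
  set.seed(2)
  for (rep in 1:10) {
    v <- sample(1:5, 9, replace = TRUE)
    g <- medianSplit(v)
    # definitional oracle: high iff value >= median
    expect_identical(g == "high", v >= median(v))
    # imbalance is bounded by the ties at the cutoff
    expect_lte(abs(sum(g == "high") - sum(g == "low")),
               2 * sum(v == median(v)))
  }
})

test_that("Kaplan-Meier estimates match hand-computed product limits", {
  km <- kmEstimator(data.frame(time = 1:4, event = 1L))
  expect_equal(km$survival, c(1, 0.75, 0.5, 0.25, 0))

  # censored-only data: survival stays at 1
  km0 <- kmEstimator(data.frame(time = c(2, 5, 7), event = 0L))
  expect_true(all(km0$survival == 1))

  # mixed censoring, hand-computed:
  # t=1 (event, 5 at risk) -> 4/5; t=2 censored; t=3 (event, 3 at risk)
  # -> 4/5 * 2/3; t=4 (event, 2 at risk) -> ... * 1/2; t=6 censored
  km2 <- kmEstimator(data.frame(time = c(1, 2, 3, 4, 6),
                                event = c(1L, 0L, 1L, 1L, 0L)))
  hand <- c(1, 4/5, 4/5, 4/5 * 2/3, 4/5 * 2/3 * 1/2, 4/5 * 2/3 * 1/2)
  expect_equal(km2$survival, hand)
  expect_equal(km2$n_risk, c(5, 5, 4, 3, 2, 1))
  expect_error(kmEstimator(data.frame(time = -1, event = 1L)), "negative")
})

test_that("Dmax matches hand-computed curve differences", {
  a <- data.frame(time = c(1, 2), event = 1L)
  expect_equal(dmaxStat(a, a)$dmax, 0)

  b <- data.frame(time = c(3, 4), event = 1L)
  dm <- dmaxStat(a, b)
  expect_equal(dm$dmax, 1)
  expect_equal(dm$time, 2)                 # achieved on [2, 3)

  # symmetric under group swap
  set.seed(8)
  g1 <- data.frame(time = rexp(20, 0.1), event = rbinom(20, 1, 0.8))
  g2 <- data.frame(time = rexp(20, 0.3), event = rbinom(20, 1, 0.8))
  expect_equal(dmaxStat(g1, g2)$dmax, dmaxStat(g2, g1)$dmax)
  expect_true(dmaxStat(g1, g2)$dmax >= 0 && dmaxStat(g1, g2)$dmax <= 1)
})

test_that("log-rank test matches the hand-computed O/E/V statistic", {
  a <- data.frame(time = c(1, 3, 5), event = c(1L, 1L, 0L))
  dup <- logrankTest(a, a)
  expect_equal(dup$chi2, 0)
  expect_equal(dup$p, 1)

  # classic small fixture, O/E/V computed by hand over pooled event times
  g1 <- data.frame(time = c(1, 2, 4), event = c(1L, 1L, 1L))
  g2 <- data.frame(time = c(3, 5, 6), event = c(1L, 1L, 0L))
  # pooled event times 1,2,3,4,5: hand computation of group-1 O - E and V
  # t=1: n=6 n1=3 d=1 e=1/2 v=(1*3*3*5)/(36*5)=1/4
  # t=2: n=5 n1=2 d=1 e=2/5 v=(2*3*4)/(25*4)=6/25
  # t=3: n=4 n1=1 d=1 e=1/4 v=(1*3*3)/(16*3)=3/16
  # t=4: n=3 n1=1 d=1 e=1/3 v=(1*2*2)/(9*2)=2/9
  # t=5: n=2 n1=0 d=1 e=0   v=0
  O <- 3; E <- 1/2 + 2/5 + 1/4 + 1/3
  V <- 1/4 + 6/25 + 3/16 + 2/9
  chi2 <- (O - E)^2 / V
  got <- logrankTest(g1, g2)
  expect_equal(got$chi2, chi2, tolerance = 1e-10)
  # invariant under relabelling
  expect_equal(logrankTest(g2, g1)$chi2, got$chi2)
  expect_error(logrankTest(data.frame(time = 1, event = 0L),
                           data.frame(time = 2, event = 0L)), "event")
})

test_that("markerTable assembles per-marker, combined and survival rows", {
  st <- simulateStudy(generatorConfig(seed = 2L, n_genes = 120L,
                                      n_mirnas = 12L, n_down_mirnas = 5L,
                                      n_activated = 3L,
                                      targets_per_mirna = 10L))
  mt <- markerTable(st$mirna, st$truth$down_mirnas, surv = st$survival)
  expect_identical(nrow(mt$per_marker), 5L)
  expect_true(all(mt$per_marker$auc >= 0 & mt$per_marker$auc <= 1))
  # planted down-regulation makes the markers discriminative
  expect_gt(mean(mt$per_marker$auc), 0.8)
  expect_false(is.null(mt$combined))
  expect_gte(mt$combined$auc, 0.5)
  expect_false(is.null(mt$survival))
  expect_true(mt$survival$dmax >= 0 && mt$survival$dmax <= 1)
})
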