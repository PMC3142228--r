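test_that("edge co-expression matches the textbook formula", {
  pe <- randomPairedExpr(20, 11, seed = 8)
  genes <- rownames(exprValues(pe))
  set.seed(88)
  edges <- t(replicate(20, sample(genes, 2)))
  co <- edgeCoexpression(pe, edges, "tumor")
  v <- exprValues(pe)[, sampleCondition(pe) == "tumor"]
  for (i in seq_len(nrow(co))) {
    ct <- cor.test(v[co$a[i], ], v[co$b[i], ])
    expect_lt(abs(co$r[i] - unname(ct$estimate)), 1e-12)
    expect_lt(abs(co$p[i] - ct$p.value), 1e-12)
  }
})

test_that("degenerate profiles are handled explicitly", {
  x <- matrix(rnorm(4 * 8, 8, 1), 4, 8)
  x[2, ] <- x[1, ]                       # identical profiles
  x[3, ] <- 5                            # constant profile
  pe <- makePairedExpr(x)
  co <- edgeCoexpression(pe, rbind(c("f001", "f002"), c("f001", "f003")),
                         "tumor")
  expect_equal(co$r[1], 1)
  expect_true(is.na(co$r[2]))
  flagged <- callCePPIs(co, r_min = 0, alpha = 1)
  expect_true(flagged$is_ceppi[1])
  expect_false(flagged$is_ceppi[2])      # undefined r is never a CePPI

  expect_message(
    co2 <- edgeCoexpression(pe, rbind(c("f001", "NOPE")), "tumor"),
    "absent")
  expect_identical(nrow(co2), 0L)
})

test_that("the CePPI rule responds to its three knobs", {
  pe <- randomPairedExpr(10, 11, seed = 2)
  genes <- rownames(exprValues(pe))
  co <- edgeCoexpression(pe, t(combn(genes[1:6], 2)), "normal")
  all_in <- callCePPIs(co, r_min = 0, alpha = 1, sign = "absolute")
  expect_true(all(all_in$is_ceppi[!is.na(all_in$r)]))
  none <- callCePPIs(co, r_min = 1.0001, alpha = 1)
  expect_false(any(none$is_ceppi))
  neg <- co; neg$r <- -abs(neg$r)
  expect_false(any(callCePPIs(neg, r_min = 0.1, alpha = 1,
                              sign = "positive")$is_ceppi))
  expect_true(any(callCePPIs(neg, r_min = 0.1, alpha = 1,
                             sign = "absolute")$is_ceppi))
})

test_that("planted co-expression factors are recovered as CePPIs", {
  hit <- vapply(1:50, function(seed) {
    set.seed(seed)
    n <- 22
    f <- rnorm(n)
    a <- 8 + f + rnorm(n, 0, 0.5)
    b <- 6 + f + rnorm(n, 0, 0.5)
    x <- matrix(rnorm(3 * 2 * n, 8, 0.5), 3, 2 * n)
    tum <- seq(1, 2 * n, 2)
    x[1, tum] <- a; x[2, tum] <- b
    pe <- makePairedExpr(x)
    co <- callCePPIs(edgeCoexpression(pe, rbind(c("f001", "f002")), "tumor"))
    co$is_ceppi[1]
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("hypergeomTail obeys its boundary identities and the summation oracle", {
  expect_equal(hypergeomTail(0, 10, 50, 100), 1.0)
  expect_equal(hypergeomTail(7, 7, 80, 80), 1.0)    # K = N: all successes
  expect_lt(abs(hypergeomTail(5, 10, 50, 1000) -
                oracleHyperTail(5, 10, 50, 1000)), 1e-12)
  expect_error(hypergeomTail(5, 4, 50, 100), "require")
  # non-increasing in k
  p <- hypergeomTail(0:10, 10, 30, 100)
  expect_true(all(diff(p) <= 1e-15))
})

test_that("fisher2x2 matches enumeration and rejects bad tables", {
  expect_error(fisher2x2(matrix(0, 2, 2)), "all-zero")
  expect_lt(abs(fisher2x2(rbind(c(5, 0), c(0, 5))) - 2 / choose(10, 5)),
            1e-12)
  tab <- rbind(c(16, 7), c(19, 20))      # activated vs remainder contrast
  expect_lt(abs(fisher2x2(tab) - oracleFisher(tab)), 1e-12)
})

test_that("network activity labels follow the enrichment contrast", {
  # background of 100 edges, 5% CePPI in tumor; one 10-edge network fully
  # co-expressed in tumor and not in normal
  genes <- sprintf("g%03d", 1:120)
  bg <- cbind(genes[seq(1, 199, 2)], genes[seq(2, 200, 2)])[1:100, ]
  key <- mirPIN:::edgeKey(bg[, 1], bg[, 2])
  net_rows <- 1:10
  mk <- function(ceppi_rows) {
    data.frame(a = bg[, 1], b = bg[, 2], key = key,
               r = ifelse(seq_len(100) %in% ceppi_rows, 0.9, 0.1),
               p = ifelse(seq_len(100) %in% ceppi_rows, 1e-4, 0.6),
               is_ceppi = seq_len(100) %in% ceppi_rows,
               stringsAsFactors = FALSE)
  }
  ceppi <- list(tumor = mk(c(net_rows, 11:15)), normal = mk(90:94))
  rp <- new("RegulatedPIN", mirna = "m", L0 = unique(as.vector(bg[net_rows, ])),
            L1 = character(), edges = bg[net_rows, , drop = FALSE])
  act <- networkActivity(rp, ceppi)
  expect_identical(act$label, "activated_tumor")
  expect_equal(act$k_tumor, 10)
  expect_lt(abs(act$p_tumor - oracleHyperTail(10, 10, 15, 100)), 1e-14)
  expect_equal(act$p_normal, oracleHyperTail(0, 10, 5, 100))

  # no CePPIs anywhere -> inactive in both conditions
  ceppi0 <- list(tumor = mk(integer()), normal = mk(integer()))
  expect_identical(networkActivity(rp, ceppi0)$label, "inactive_both")

  # empty network -> inactive with p = 1
  rp0 <- new("RegulatedPIN", mirna = "m0", L0 = "g001", L1 = character(),
             edges = matrix(character(), 0, 2))
  act0 <- suppressMessages(networkActivity(rp0, ceppi))
  expect_identical(act0$label, "inactive_both")
  expect_equal(act0$p_tumor, 1.0)
})

test_that("activity labels ignore edge order and sample order", {
  cfg <- generatorConfig(seed = 6L, n_genes = 200L, n_mirnas = 10L,
                         n_down_mirnas = 4L, n_activated = 2L,
                         targets_per_mirna = 15L)
  st <- simulateStudy(cfg, go = FALSE, survival = FALSE)
  bg <- networkEdges(st$pin)
  ceppi <- lapply(c(tumor = "tumor", normal = "normal"), function(cond)
    callCePPIs(edgeCoexpression(st$mrna, bg, cond)))
  tr <- st$truth
  mir <- tr$activated_mirnas[1]
  rp <- buildRegulatedPIN(mir, tr$shifted_targets[[mir]], st$targets, st$pin)
  base <- networkActivity(rp, ceppi)

  set.seed(2)
  perm <- sample(nrow(bg))
  ceppi_shuf <- lapply(ceppi, function(df) df[perm, ])
  expect_identical(networkActivity(rp, ceppi_shuf)$label, base$label)

  # permute tumor columns within condition: correlations are unchanged
  v <- exprValues(st$mrna)
  cond <- sampleCondition(st$mrna)
  tum <- which(cond == "tumor")
  v2 <- v; v2[, tum] <- v[, sample(tum)]
  pe2 <- PairedExpression(v2, cond, pairId(st$mrna))
  ceppi2 <- lapply(c(tumor = "tumor", normal = "normal"), function(cc)
    callCePPIs(edgeCoexpression(pe2, bg, cc)))
  expect_identical(networkActivity(rp, ceppi2)$label, base$label)
})
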