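test_that("PIN generation honours the requested model and is deterministic", {
  cfg <- generatorConfig(n_genes = 4L, n_mirnas = 2L, n_down_mirnas = 1L,
                         n_activated = 1L, pin_model = "erdos_renyi",
                         pin_edges_param = 6L, targets_per_mirna = 3L,
                         seed = 3L)
  pin <- generatePIN(cfg)
  expect_identical(numEdges(pin), 6L)           # complete graph on 4 nodes
  expect_identical(networkEdges(generatePIN(cfg)), networkEdges(pin))

  cfg2 <- generatorConfig(n_genes = 500L, pin_edges_param = 3L, seed = 11L)
  pin2 <- generatePIN(cfg2)
  # closed-form Barabasi-Albert edge count: node i > 1 adds min(m, i - 1)
  m <- 3L
  expect_identical(numEdges(pin2),
                   as.integer((500L - m) * m + m * (m - 1) / 2))
  # independently coded reference generator gives the same count
  ref_edges <- 0L
  for (i in 2:500) ref_edges <- ref_edges + min(m, i - 1L)
  expect_identical(numEdges(pin2), ref_edges)
  expect_error(generatePIN(generatorConfig(n_genes = 4L, n_mirnas = 0L,
                                           n_down_mirnas = 0L,
                                           n_activated = 0L,
                                           pin_model = "erdos_renyi",
                                           targets_per_mirna = 2L,
                                           pin_edges_param = 7L)),
               "edge count")
})

test_that("target maps are uniform samples without replacement", {
  cfg <- generatorConfig(n_genes = 40L, n_mirnas = 2L, n_down_mirnas = 1L,
                         n_activated = 1L, targets_per_mirna = 40L,
                         pin_model = "erdos_renyi", pin_edges_param = 100L)
  pin <- generatePIN(cfg)
  tm <- generateTargetMap(cfg, pin)
  expect_true(all(vapply(tm, function(g)
    setequal(g, networkNodes(pin)), logical(1))))   # exhaustive case

  cfg0 <- generatorConfig(n_genes = 40L, n_mirnas = 0L, n_down_mirnas = 0L,
                          n_activated = 0L, targets_per_mirna = 5L,
                          pin_model = "erdos_renyi", pin_edges_param = 100L)
  expect_length(generateTargetMap(cfg0, pin), 0L)

  # per-gene in-degree ~ Binomial(n_mirnas, targets/n_genes); check the
  # pooled counts stay inside central 99% binomial bounds
  cfgU <- generatorConfig(n_genes = 100L, n_mirnas = 50L,
                          n_down_mirnas = 1L, n_activated = 1L,
                          targets_per_mirna = 30L,
                          pin_model = "erdos_renyi", pin_edges_param = 200L,
                          seed = 5L)
  pinU <- generatePIN(cfgU)
  tmU <- generateTargetMap(cfgU, pinU)
  indeg <- table(factor(unlist(tmU, use.names = FALSE),
                        levels = networkNodes(pinU)))
  bounds <- qbinom(c(0.005, 0.995), 50L, 30 / 100)
  expect_gt(mean(indeg >= bounds[1] & indeg <= bounds[2]), 0.95)
})

test_that("expression generator realises the planted paired shift", {
  base <- list(n_genes = 30L, n_mirnas = 6L, n_down_mirnas = 3L,
               n_activated = 2L, targets_per_mirna = 10L,
               pin_model = "erdos_renyi", pin_edges_param = 60L)
  diffs <- vapply(seq_len(200), function(seed) {
    cfg <- do.call(generatorConfig, c(base, list(seed = seed)))
    pin <- generatePIN(cfg)
    ex <- generateExpression(cfg, pin, generateTargetMap(cfg, pin))
    z <- pairedDiffs(ex$mirna)
    mean(z[ex$truth$down_mirnas, ])
  }, numeric(1))
  expect_lt(abs(mean(diffs) + 1.5), 0.05)
})

test_that("expression generator is deterministic and supports a pure null", {
  cfg <- generatorConfig(n_genes = 30L, n_mirnas = 6L, n_down_mirnas = 3L,
                         n_activated = 2L, targets_per_mirna = 10L,
                         pin_model = "erdos_renyi", pin_edges_param = 60L,
                         seed = 9L)
  pin <- generatePIN(cfg)
  tm <- generateTargetMap(cfg, pin)
  ex1 <- generateExpression(cfg, pin, tm)
  ex2 <- generateExpression(cfg, pin, tm)
  expect_identical(exprValues(ex1$mirna), exprValues(ex2$mirna))
  expect_identical(exprValues(ex1$mrna), exprValues(ex2$mrna))

  cfg0 <- do.call(generatorConfig,
                  c(cfg[c("n_genes", "n_mirnas", "n_down_mirnas",
                          "n_activated", "targets_per_mirna", "pin_model",
                          "pin_edges_param", "seed")],
                    list(mirna_shift = 0, target_shift = 0,
                         activation_loading = 0)))
  ex0 <- generateExpression(cfg0, pin, tm)
  expect_length(ex0$truth$down_mirnas, 3L)       # recorded but effectless
  z <- pairedDiffs(ex0$mirna)
  expect_lt(abs(mean(z[ex0$truth$down_mirnas, ])), 0.2)

  cfg_bad <- do.call(generatorConfig,
                     c(cfg[c("n_genes", "n_mirnas", "n_down_mirnas",
                             "n_activated", "targets_per_mirna",
                             "pin_model", "pin_edges_param")],
                       list(n_pairs = 2L)))
  expect_error(generateExpression(cfg_bad, pin, tm), "3 sample pairs")
})

test_that("planted down-miRNAs realise fold change <= 1/2 almost always", {
  hits <- vapply(1:10, function(seed) {
    cfg <- generatorConfig(seed = seed, n_genes = 60L, n_mirnas = 20L,
                           n_down_mirnas = 10L, n_activated = 5L,
                           targets_per_mirna = 12L,
                           pin_model = "erdos_renyi",
                           pin_edges_param = 150L)
    pin <- generatePIN(cfg)
    ex <- generateExpression(cfg, pin, generateTargetMap(cfg, pin))
    fc <- 2^rowMeans(pairedDiffs(ex$mirna)[ex$truth$down_mirnas, ])
    mean(fc <= 0.5)
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
})

test_that("survival generator matches its exponential model", {
  sv <- generateSurvival(60L, 1, 0.05, censor_rate = 0, seed = 1L)
  expect_true(all(sv$event == 1L))               # no censoring limit

  ratios <- vapply(seq_len(200), function(seed) {
    sv <- generateSurvival(200L, 3, 0.1, 0, seed = seed)
    med <- function(g) {
      km <- kmEstimator(sv[sv$group == g, ])
      km$time[which(km$survival <= 0.5)[1]]
    }
    med("high") / med("low")
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 3), 0.6)          # exp median = ln2 / rate

  dnull <- vapply(seq_len(500), function(seed) {
    sv <- generateSurvival(60L, 1, 0.05, 0.02, seed = seed)
    grp <- medianSplit(sv$marker)
    dmaxStat(sv[grp == "high", ], sv[grp == "low", ])$dmax
  }, numeric(1))
  expect_lt(median(dnull), 0.25)

  expect_error(generateSurvival(1L, 1, 0.1, 0), "2 subjects")
})

test_that("toy GO generator yields a rooted DAG with propagated leaves", {
  genes <- sprintf("G%02d", 1:40)
  go1 <- generateGO(1L, genes, c(5L, 10L), seed = 2L)
  expect_identical(go1$terms, "T0001")
  expect_true(length(go1$term2gene$T0001) >= 5)

  sizes_ok <- vapply(seq_len(100), function(seed) {
    go <- generateGO(12L, genes, c(5L, 20L), depth = 3L, seed = seed)
    leaves <- setdiff(go$terms, go$dag[, "parent"])
    direct <- lengths(go$direct[leaves])
    all(direct >= 5 & direct <= 20)
  }, logical(1))
  expect_true(all(sizes_ok))

  go <- generateGO(15L, genes, c(4L, 8L), depth = 3L, seed = 7L)
  anc <- mirPIN:::goAncestors(go$dag)
  for (tt in names(go$direct))
    for (a in anc[[tt]])
      expect_true(all(go$direct[[tt]] %in% go$term2gene[[a]]))
})
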