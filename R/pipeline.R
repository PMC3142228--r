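#' Pipeline run configuration
#'
#' Validated bundle of every stage's parameters. Defaults follow the
#' shipped analysis: SAM delta 5 with fold change 2 and 1000 permutations,
#' CePPI rule r >= 0.5 at p <= 0.05 (positive sign), activation threshold
#' 0.05, induced-subgraph edge rule, robustness removal fractions
#' 5/10/15/20% with 1000 repetitions, enrichment p <= 0.001 with minimum
#' term size 3.
#'
#' @param sam.delta,sam.fold_change,sam.n_perm SAM calling parameters.
#' @param ceppi.r_min,ceppi.alpha,ceppi.sign CePPI rule.
#' @param activity.alpha activation threshold.
#' @param activity.adjust "none" or "BH" across networks.
#' @param netbuild.edges "induced" or "l0_incident".
#' @param robustness.fractions,robustness.reps robustness stage parameters.
#' @param enrich.p_max,enrich.min_term enrichment stage parameters.
#' @param seed master seed governing all randomness in a run.
#' @return validated list of class \code{"RunConfig"}.
#' @export
runConfig <- function(sam.delta = 5, sam.fold_change = 2,
                      sam.n_perm = 1000L, ceppi.r_min = 0.5,
                      ceppi.alpha = 0.05,
                      ceppi.sign = c("positive", "absolute"),
                      activity.alpha = 0.05,
                      activity.adjust = c("none", "BH"),
                      netbuild.edges = c("induced", "l0_incident"),
                      robustness.fractions = c(0.05, 0.1, 0.15, 0.2),
                      robustness.reps = 1000L, enrich.p_max = 0.001,
                      enrich.min_term = 3L, seed = 1L) {
  cfg <- list(sam.delta = sam.delta, sam.fold_change = sam.fold_change,
              sam.n_perm = as.integer(sam.n_perm),
              ceppi.r_min = ceppi.r_min, ceppi.alpha = ceppi.alpha,
              ceppi.sign = match.arg(ceppi.sign),
              activity.alpha = activity.alpha,
              activity.adjust = match.arg(activity.adjust),
              netbuild.edges = match.arg(netbuild.edges),
              robustness.fractions = robustness.fractions,
              robustness.reps = as.integer(robustness.reps),
              enrich.p_max = enrich.p_max,
              enrich.min_term = as.integer(enrich.min_term),
              seed = as.integer(seed))
  if (cfg$sam.delta < 0) stop("sam.delta must be >= 0")
  if (cfg$sam.fold_change < 1) stop("sam.fold_change must be >= 1")
  if (cfg$sam.n_perm < 1L) stop("sam.n_perm must be >= 1")
  if (cfg$ceppi.r_min < 0) stop("ceppi.r_min must be >= 0")
  for (p in c("ceppi.alpha", "activity.alpha", "enrich.p_max"))
    if (cfg[[p]] <= 0 || cfg[[p]] > 1) stop(p, " must lie in (0, 1]")
  if (any(cfg$robustness.fractions < 0 | cfg$robustness.fractions >= 1))
    stop("robustness.fractions must lie in [0, 1)")
  if (cfg$robustness.reps < 1L) stop("robustness.reps must be >= 1")
  if (cfg$enrich.min_term < 1L) stop("enrich.min_term must be >= 1")
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a RunConfig from a YAML key-value file
#'
#' Keys are the argument names of \code{\link{runConfig}}; unknown keys are
#' an error.
#'
#' @param path YAML file path.
#' @return a validated \code{"RunConfig"}.
#' @export
readRunConfig <- function(path) {
  kv <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  bad <- setdiff(names(kv), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(runConfig, kv)
}

stageLog <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the integrated analysis end to end
#'
#' Stage order: paired SAM on the miRNA and mRNA matrices; subnetwork
#' construction for the down-regulated miRNAs from their up-regulated
#' targets; CePPI calling over the whole PIN and activity labelling;
#' robustness to random edge removal; GO enrichment comparison of L0 vs
#' L0 u L1 per network; marker evaluation (AUC per called miRNA, combined
#' panel, optional survival analysis). When ground truth is supplied,
#' truth-vs-called confusion counts are added to the summary.
#'
#' @param data list with elements mirna, mrna (both
#'   \linkS4class{PairedExpression}), pin, targets, and optionally go,
#'   survival, truth — as returned by \code{\link{simulateStudy}} or
#'   assembled from the \code{read*} parsers.
#' @param config a \code{\link{runConfig}}.
#' @param stages character subset of
#'   c("diffexpr","netbuild","activity","robustness","enrich","markers");
#'   stages are always executed in this order and each requires its
#'   predecessors up to "activity".
#' @param outdir optional directory; when given, stage TSVs, a run summary
#'   JSON and GraphML exports are written via \code{\link{exportResults}}.
#' @return list of stage results plus a \code{summary} list.
#' @export
runPipeline <- function(data, config = runConfig(),
                        stages = c("diffexpr", "netbuild", "activity",
                                   "robustness", "enrich", "markers"),
                        outdir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  all_stages <- c("diffexpr", "netbuild", "activity", "robustness",
                  "enrich", "markers")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  res <- list(config = config)
  run_stage <- function(stage, fn) {
    if (!stage %in% stages) return(invisible(NULL))
    tryCatch(fn(), error = function(e) {
      if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        writeLines(paste("stage", stage, "failed:", conditionMessage(e)),
                   file.path(outdir, "FAILED"))
      }
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  run_stage("diffexpr", function() {
    res$sam_mirna <<- samCall(data$mirna, delta = config$sam.delta,
                              fc_min = config$sam.fold_change,
                              n_perm = config$sam.n_perm,
                              seed = config$seed + 10L)
    res$sam_mrna <<- samCall(data$mrna, delta = config$sam.delta,
                             fc_min = config$sam.fold_change,
                             n_perm = config$sam.n_perm,
                             seed = config$seed + 11L)
    stageLog("diffexpr", nrow(samTable(res$sam_mirna)), " miRNAs / ",
             nrow(samTable(res$sam_mrna)), " genes; down miRNAs: ",
             length(calledFeatures(res$sam_mirna, "down")),
             ", up genes: ", length(calledFeatures(res$sam_mrna, "up")))
  })

  run_stage("netbuild", function() {
    down <- calledFeatures(res$sam_mirna, "down")
    up <- calledFeatures(res$sam_mrna, "up")
    res$networks <<- buildAllPINs(down, up, data$targets, data$pin,
                                  edge_rule = config$netbuild.edges)
    stageLog("netbuild", length(res$networks), " networks from ",
             length(down), " down-regulated miRNAs")
  })

  run_stage("activity", function() {
    bg <- networkEdges(data$pin)
    res$ceppi <<- lapply(c(tumor = "tumor", normal = "normal"),
      function(cond)
        callCePPIs(edgeCoexpression(data$mrna, bg, cond),
                   r_min = config$ceppi.r_min, alpha = config$ceppi.alpha,
                   sign = config$ceppi.sign))
    res$activity <<- activityTable(res$networks, res$ceppi,
                                   alpha_act = config$activity.alpha,
                                   adjust = config$activity.adjust)
    stageLog("activity", sum(res$activity$label == "activated_tumor"),
             " of ", nrow(res$activity), " networks activated in tumor")
    if (!is.null(data$truth) && length(data$truth$down_mirnas)) {
      ## parameter-recovery view: label the planted networks themselves,
      ## so activity calling is assessed independently of upstream DE recall
      pl <- lapply(data$truth$down_mirnas, function(mir)
        buildRegulatedPIN(mir, data$truth$shifted_targets[[mir]],
                          data$targets, data$pin,
                          edge_rule = config$netbuild.edges))
      names(pl) <- data$truth$down_mirnas
      pl <- Filter(Negate(is.null), pl)
      res$planted_networks <<- pl
      res$planted_activity <<- activityTable(
        pl, res$ceppi, alpha_act = config$activity.alpha,
        adjust = config$activity.adjust)
    }
  })

  run_stage("robustness", function() {
    act <- res$activity$mirna[res$activity$label %in%
                                c("activated_tumor", "activated_both")]
    if (!length(act)) {
      stageLog("robustness", "no tumor-activated networks; skipped")
      res$robustness <<- NULL
      return(invisible(NULL))
    }
    l0s <- lapply(res$networks[act], L0)
    res$robustness <<- robustnessTest(
      data$pin, l0s, res$ceppi$tumor,
      fractions = config$robustness.fractions,
      n_reps = config$robustness.reps, alpha_act = config$activity.alpha,
      edge_rule = config$netbuild.edges, seed = config$seed + 20L)
    stageLog("robustness", "mean retention: ",
             paste(signif(res$robustness$summary$mean_retention, 3),
                   collapse = " "))
  })

  run_stage("enrich", function() {
    if (is.null(data$go)) {
      stageLog("enrich", "no GO annotation supplied; skipped")
      res$enrich <<- NULL
      return(invisible(NULL))
    }
    universe <- intersect(networkNodes(data$pin),
                          unique(unlist(data$go$term2gene,
                                        use.names = FALSE)))
    res$enrich <<- do.call(rbind, lapply(res$networks, function(rp) {
      cmp <- tryCatch(compareLevels(rp, data$go, universe,
                                    p_max = config$enrich.p_max,
                                    min_term = config$enrich.min_term),
                      error = function(e) NULL)
      if (is.null(cmp)) return(NULL)
      cbind(data.frame(mirna = mirnaId(rp), stringsAsFactors = FALSE), cmp)
    }))
    if (!is.null(res$enrich)) rownames(res$enrich) <- NULL
    stageLog("enrich", if (is.null(res$enrich)) 0L else
             nrow(res$enrich) / 2L, " networks compared (L0 vs union)")
  })

  run_stage("markers", function() {
    down <- calledFeatures(res$sam_mirna, "down")
    res$markers <<- markerTable(data$mirna, down, direction = "lower",
                                surv = data$survival)
    stageLog("markers", length(down), " markers evaluated")
  })

  res$summary <- pipelineSummary(res, data)
  if (!is.null(outdir)) exportResults(res, outdir)
  res
}

pipelineSummary <- function(res, data) {
  sm <- list(seed = res$config$seed,
             parameters = unclass(res$config))
  if (!is.null(res$sam_mirna)) {
    down <- calledFeatures(res$sam_mirna, "down")
    sm$n_down_mirnas <- length(down)
    sm$n_up_genes <- length(calledFeatures(res$sam_mrna, "up"))
    sm$sam_fdr_mirna <- res$sam_mirna@fdr
  }
  if (!is.null(res$networks)) sm$n_networks <- length(res$networks)
  if (!is.null(res$activity) && nrow(res$activity)) {
    sm$n_activated_tumor <- sum(res$activity$label == "activated_tumor")
    sm$activity_labels <- as.list(table(res$activity$label))
  }
  if (!is.null(res$robustness))
    sm$retention <- stats::setNames(
      as.list(res$robustness$summary$mean_retention),
      paste0("f", res$robustness$summary$fraction))
  if (!is.null(data$truth) && !is.null(res$sam_mirna)) {
    truth <- data$truth
    down <- calledFeatures(res$sam_mirna, "down")
    all_mirs <- samTable(res$sam_mirna)$feature
    sm$confusion_down_mirnas <- list(
      tp = length(intersect(down, truth$down_mirnas)),
      fp = length(setdiff(down, truth$down_mirnas)),
      fn = length(setdiff(truth$down_mirnas, down)),
      tn = length(setdiff(setdiff(all_mirs, truth$down_mirnas), down)))
    if (!is.null(res$planted_activity) && nrow(res$planted_activity)) {
      pa <- res$planted_activity
      act <- pa$mirna[pa$label %in% c("activated_tumor", "activated_both")]
      planted <- truth$activated_mirnas
      sm$activation_sensitivity <-
        length(intersect(act, planted)) / length(planted)
      nonact <- setdiff(truth$down_mirnas, planted)
      if (length(nonact))
        sm$activation_specificity <-
          length(setdiff(nonact, act)) / length(nonact)
    }
    if (!is.null(res$activity) && nrow(res$activity))
      sm$discovered_activated_tumor <-
        sum(res$activity$label == "activated_tumor")
  }
  sm
}

#' Export pipeline results to a run directory
#'
#' Writes per-stage TSVs (SAM tables, network membership and edges,
#' activity states, robustness retention, enrichment comparison, marker
#' statistics), a \code{summary.json}, and one GraphML file per regulated
#' network.
#'
#' @param res result list from \code{\link{runPipeline}}.
#' @param outdir output directory (created if needed).
#' @param graphml logical; write GraphML per network.
#' @return invisibly, \code{outdir}.
#' @export
exportResults <- function(res, outdir, graphml = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(res$sam_mirna))
    writeTsv(samTable(res$sam_mirna), file.path(outdir, "sam_mirna.tsv"))
  if (!is.null(res$sam_mrna))
    writeTsv(samTable(res$sam_mrna), file.path(outdir, "sam_mrna.tsv"))
  if (!is.null(res$networks)) {
    memb <- do.call(rbind, lapply(res$networks, function(rp)
      data.frame(mirna = mirnaId(rp),
                 gene = c(L0(rp), L1(rp)),
                 layer = c(rep("L0", length(L0(rp))),
                           rep("L1", length(L1(rp)))),
                 stringsAsFactors = FALSE)))
    if (is.null(memb))
      memb <- data.frame(mirna = character(), gene = character(),
                         layer = character())
    writeTsv(memb, file.path(outdir, "network_membership.tsv"))
    eds <- do.call(rbind, lapply(res$networks, function(rp) {
      e <- networkEdges(rp)
      if (!nrow(e)) return(NULL)
      data.frame(mirna = mirnaId(rp), gene_a = e[, 1L], gene_b = e[, 2L],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(eds))
      eds <- data.frame(mirna = character(), gene_a = character(),
                        gene_b = character())
    writeTsv(eds, file.path(outdir, "network_edges.tsv"))
    if (graphml)
      for (rp in res$networks)
        exportGraphML(rp, file.path(outdir,
                                    paste0("network_", mirnaId(rp),
                                           ".graphml")))
  }
  if (!is.null(res$activity))
    writeTsv(res$activity, file.path(outdir, "activity.tsv"))
  if (!is.null(res$planted_activity))
    writeTsv(res$planted_activity, file.path(outdir, "activity_planted.tsv"))
  if (!is.null(res$robustness)) {
    per <- data.frame(mirna = rownames(res$robustness$per_network),
                      res$robustness$per_network, check.names = FALSE,
                      stringsAsFactors = FALSE)
    writeTsv(per, file.path(outdir, "robustness_per_network.tsv"))
    writeTsv(res$robustness$summary, file.path(outdir, "robustness.tsv"))
  }
  if (!is.null(res$enrich))
    writeTsv(res$enrich, file.path(outdir, "enrichment_coverage.tsv"))
  if (!is.null(res$markers)) {
    if (!is.null(res$markers$per_marker))
      writeTsv(res$markers$per_marker, file.path(outdir, "markers.tsv"))
    if (!is.null(res$markers$combined))
      writeTsv(res$markers$combined, file.path(outdir,
                                               "markers_combined.tsv"))
    if (!is.null(res$markers$survival))
      writeTsv(res$markers$survival, file.path(outdir,
                                               "markers_survival.tsv"))
  }
  jsonlite::write_json(res$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
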