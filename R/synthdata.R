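#' Configuration of the synthetic study generator
#'
#' Bundles and validates every knob of the synthetic paired tumor/normal
#' study. Defaults mirror the scale of a 22-pair tumor/normal design with
#' 23 down-regulated miRNAs, 16 of whose regulated subnetworks are
#' "activated" in tumors by a per-network latent co-expression factor.
#'
#' @param n_genes number of mRNA features (= PIN node universe).
#' @param n_mirnas number of miRNA features.
#' @param n_pairs number of tumor/normal sample pairs.
#' @param pin_model random-graph model for the synthetic PIN.
#' @param pin_edges_param edges parameter: attachment count m for
#'   preferential attachment, total edge count for Erdos-Renyi.
#' @param targets_per_mirna predicted targets sampled per miRNA.
#' @param n_down_mirnas number of miRNAs planted as tumor-down-regulated.
#' @param n_activated of those, how many get an activated subnetwork.
#' @param mirna_shift,target_shift planted log2 shifts (miRNA down in tumor,
#'   a fraction of its targets up in tumor).
#' @param target_fraction fraction of a planted miRNA's targets that are
#'   shifted up (at least 3 targets are always shifted).
#' @param baseline_mean_mu,baseline_mean_sd per-feature baseline mean model.
#' @param residual_sd per-value measurement noise (log2 units).
#' @param pair_effect_sd per-feature, per-pair shared effect (cancels in the
#'   paired difference).
#' @param activation_loading loading of the per-network latent factor added
#'   to genes incident to an activated subnetwork's edges in tumor samples.
#' @param background_coexp_fraction fraction of all PIN edges given a weak
#'   (loading 0.5) shared factor in both conditions, creating a
#'   non-degenerate background co-expression rate.
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @return a validated list of class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(n_genes = 4000L, n_mirnas = 62L, n_pairs = 22L,
                            pin_model = c("preferential_attachment",
                                          "erdos_renyi"),
                            pin_edges_param = 3L, targets_per_mirna = 60L,
                            n_down_mirnas = 23L, n_activated = 16L,
                            mirna_shift = 1.5, target_shift = 1.5,
                            target_fraction = 0.3, baseline_mean_mu = 8,
                            baseline_mean_sd = 2, residual_sd = 0.5,
                            pair_effect_sd = 0.5, activation_loading = 1,
                            background_coexp_fraction = 0.05, seed = 1L) {
  pin_model <- match.arg(pin_model)
  cfg <- list(n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
              n_pairs = as.integer(n_pairs), pin_model = pin_model,
              pin_edges_param = as.integer(pin_edges_param),
              targets_per_mirna = as.integer(targets_per_mirna),
              n_down_mirnas = as.integer(n_down_mirnas),
              n_activated = as.integer(n_activated),
              mirna_shift = mirna_shift, target_shift = target_shift,
              target_fraction = target_fraction,
              baseline_mean_mu = baseline_mean_mu,
              baseline_mean_sd = baseline_mean_sd,
              residual_sd = residual_sd, pair_effect_sd = pair_effect_sd,
              activation_loading = activation_loading,
              background_coexp_fraction = background_coexp_fraction,
              seed = as.integer(seed))
  if (cfg$n_genes < 3L) stop("n_genes must be >= 3")
  if (cfg$n_mirnas < 0L) stop("n_mirnas must be >= 0")
  if (!(cfg$n_activated <= cfg$n_down_mirnas &&
        cfg$n_down_mirnas <= cfg$n_mirnas))
    stop("need n_activated <= n_down_mirnas <= n_mirnas")
  for (p in c("baseline_mean_sd", "residual_sd", "pair_effect_sd"))
    if (cfg[[p]] <= 0) stop(p, " must be > 0")
  for (p in c("target_fraction", "background_coexp_fraction"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  if (cfg$targets_per_mirna > cfg$n_genes)
    stop("targets_per_mirna cannot exceed n_genes")
  class(cfg) <- "GeneratorConfig"
  cfg
}

geneUniverse <- function(n) sprintf("G%05d", seq_len(n))
mirnaUniverse <- function(n) sprintf("miR-S%03d", seq_len(n))

#' Generate a synthetic protein interaction network
#'
#' Draws a simple undirected random graph over the gene universe, either by
#' preferential attachment (scale-free-ish degree distribution, as in curated
#' human interactomes) or as an Erdos-Renyi G(n, m) graph.
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @return an \linkS4class{InteractionNetwork} with the full gene universe as
#'   node set (Erdos-Renyi graphs may contain isolated nodes).
#' @export
generatePIN <- function(cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  n <- cfg$n_genes
  m <- cfg$pin_edges_param
  set.seed(cfg$seed)
  g <- switch(cfg$pin_model,
    preferential_attachment = {
      if (m < 1L || m >= n)
        stop("preferential attachment needs 1 <= pin_edges_param < n_genes")
      igraph::sample_pa(n, m = m, directed = FALSE, algorithm = "psumtree")
    },
    erdos_renyi = {
      if (m < 0L || m > n * (n - 1) / 2)
        stop("erdos_renyi edge count must lie in [0, n(n-1)/2]")
      igraph::sample_gnm(n, m)
    })
  genes <- geneUniverse(n)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- cbind(genes[el[, 1L]], genes[el[, 2L]])
  InteractionNetwork(edges, nodes = genes)
}

#' Generate a synthetic miRNA -> target map
#'
#' Each miRNA receives exactly \code{targets_per_mirna} distinct targets
#' sampled uniformly without replacement from the gene universe.
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @param pin the \linkS4class{InteractionNetwork} defining the gene universe.
#' @return a named list: miRNA id -> character vector of target genes.
#' @export
generateTargetMap <- function(cfg, pin) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  genes <- networkNodes(pin)
  if (cfg$targets_per_mirna > length(genes))
    stop("targets_per_mirna cannot exceed the gene universe")
  set.seed(cfg$seed + 1L)
  mirs <- mirnaUniverse(cfg$n_mirnas)
  tm <- lapply(mirs, function(m) sort(sample(genes, cfg$targets_per_mirna)))
  names(tm) <- mirs
  tm
}

#' Generate paired tumor/normal expression with planted effects
#'
#' Per log2 value the model is
#' \deqn{x = \mu_f + pair_{f,p} + shift + activation + \epsilon,}
#' where \eqn{\mu_f ~ N(baseline\_mean\_mu, baseline\_mean\_sd)},
#' \eqn{pair_{f,p} ~ N(0, pair\_effect\_sd)} is shared by the two samples of
#' a pair (and therefore cancels in the paired difference), and
#' \eqn{\epsilon ~ N(0, residual\_sd)}. Planted structure: each of
#' \code{n_down_mirnas} randomly chosen miRNAs is shifted down by
#' \code{mirna_shift} in tumor samples; a random fraction
#' \code{target_fraction} (never fewer than 3) of its targets is shifted up
#' by \code{target_shift} in tumor. For \code{n_activated} of those miRNAs
#' the true regulated subnetwork (built from the shifted targets) receives a
#' per-tumor-sample latent factor: \code{activation_loading * f_s} is added
#' to every gene incident to the subnetwork's edges, in tumor samples only
#' (overlapping subnetworks add their factors). A fraction
#' \code{background_coexp_fraction} of all PIN edges receives an analogous
#' weak factor (loading 0.5) in both conditions.
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @param pin the PIN over the gene universe.
#' @param targets a target map as from \code{\link{generateTargetMap}}.
#' @return list with elements \code{mirna} and \code{mrna} (both
#'   \linkS4class{PairedExpression}) and \code{truth}: a list with
#'   \code{down_mirnas}, \code{activated_mirnas}, \code{shifted_targets}
#'   (per-miRNA gene sets) and \code{activated_edges} (per-miRNA edge
#'   matrices).
#' @export
generateExpression <- function(cfg, pin, targets) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  if (cfg$n_pairs < 3L)
    stop("need at least 3 sample pairs")
  genes <- networkNodes(pin)
  if (!all(unique(unlist(targets, use.names = FALSE)) %in% genes))
    stop("target map refers to genes outside the PIN universe")
  mirs <- names(targets)
  np <- cfg$n_pairs
  pairs <- sprintf("P%02d", seq_len(np))
  samples <- as.vector(rbind(paste0(pairs, "T"), paste0(pairs, "N")))
  cond <- rep(c("tumor", "normal"), np)
  pid <- rep(pairs, each = 2L)
  tumor_cols <- which(cond == "tumor")

  set.seed(cfg$seed + 2L)

  draw_matrix <- function(features) {
    p <- length(features)
    mu <- stats::rnorm(p, cfg$baseline_mean_mu, cfg$baseline_mean_sd)
    pe <- matrix(stats::rnorm(p * np, 0, cfg$pair_effect_sd), p, np)
    x <- matrix(mu, p, 2L * np) + pe[, rep(seq_len(np), each = 2L)]
    dimnames(x) <- list(features, samples)
    x
  }

  xm <- draw_matrix(mirs)
  xg <- draw_matrix(genes)

  down <- if (cfg$n_down_mirnas) sort(sample(mirs, cfg$n_down_mirnas))
          else character()
  activated <- if (cfg$n_activated) sort(sample(down, cfg$n_activated))
               else character()

  shifted <- lapply(down, function(m) {
    tg <- targets[[m]]
    k <- max(3L, round(cfg$target_fraction * length(tg)))
    if (length(tg) < 3L)
      stop("planted miRNAs need at least 3 predicted targets")
    sort(sample(tg, min(k, length(tg))))
  })
  names(shifted) <- down

  if (length(down)) {
    xm[down, tumor_cols] <- xm[down, tumor_cols] - cfg$mirna_shift
    up_genes <- unique(unlist(shifted, use.names = FALSE))
    xg[up_genes, tumor_cols] <- xg[up_genes, tumor_cols] + cfg$target_shift
  }

  activated_edges <- list()
  for (m in activated) {
    rp <- buildRegulatedPIN(m, shifted[[m]], targets, pin)
    activated_edges[[m]] <- if (is.null(rp)) matrix(character(), 0L, 2L)
                            else networkEdges(rp)
    if (!is.null(rp) && nrow(networkEdges(rp))) {
      incident <- unique(as.vector(networkEdges(rp)))
      f <- stats::rnorm(np)
      xg[incident, tumor_cols] <- xg[incident, tumor_cols] +
        cfg$activation_loading * rep(f, each = length(incident))
    }
  }

  ed <- networkEdges(pin)
  nbg <- floor(cfg$background_coexp_fraction * nrow(ed))
  if (nbg > 0L) {
    bg <- sample(nrow(ed), nbg)
    for (i in bg) {
      g <- stats::rnorm(2L * np)
      xg[ed[i, 1L], ] <- xg[ed[i, 1L], ] + 0.5 * g
      xg[ed[i, 2L], ] <- xg[ed[i, 2L], ] + 0.5 * g
    }
  }

  xm <- xm + matrix(stats::rnorm(length(xm), 0, cfg$residual_sd), nrow(xm))
  xg <- xg + matrix(stats::rnorm(length(xg), 0, cfg$residual_sd), nrow(xg))

  list(mirna = PairedExpression(xm, cond, pid),
       mrna = PairedExpression(xg, cond, pid),
       truth = list(down_mirnas = down, activated_mirnas = activated,
                    shifted_targets = shifted,
                    activated_edges = activated_edges))
}

#' Generate synthetic two-group survival data
#'
#' Exponential event times with an exponential censoring process; the cohort
#' is split into two equal-size groups whose hazards differ by
#' \code{group_hr}. The marker value is drawn higher in the low-hazard group
#' (a protective marker), so median-split survival analyses see a planted
#' signal when \code{group_hr > 1}.
#'
#' @param n_subjects cohort size (>= 2).
#' @param group_hr hazard ratio of group "low" relative to group "high"
#'   marker.
#' @param baseline_rate event hazard (per month) in the high-marker group.
#' @param censor_rate censoring hazard; 0 disables censoring.
#' @param seed integer seed.
#' @return data.frame with columns subject, time, event (0/1), marker,
#'   group.
#' @export
generateSurvival <- function(n_subjects, group_hr, baseline_rate,
                             censor_rate, seed = 1L) {
  if (n_subjects < 2L) stop("need at least 2 subjects")
  if (baseline_rate <= 0 || group_hr <= 0) stop("rates and hr must be > 0")
  if (censor_rate < 0) stop("censor_rate must be >= 0")
  set.seed(as.integer(seed))
  n_hi <- floor(n_subjects / 2)
  group <- c(rep("high", n_hi), rep("low", n_subjects - n_hi))
  rate <- ifelse(group == "high", baseline_rate, baseline_rate * group_hr)
  t_event <- stats::rexp(n_subjects, rate)
  t_cens <- if (censor_rate > 0) stats::rexp(n_subjects, censor_rate)
            else rep(Inf, n_subjects)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  marker <- stats::rnorm(n_subjects, mean = ifelse(group == "high", 1, 0),
                         sd = 0.5)
  data.frame(subject = sprintf("S%03d", seq_len(n_subjects)),
             time = time, event = event, marker = marker, group = group,
             stringsAsFactors = FALSE)
}

#' Generate a toy GO annotation and DAG
#'
#' Builds a random rooted DAG of terms connected by is_a (child -> parent)
#' edges, annotates genes to leaf terms with sizes drawn uniformly from
#' \code{term_size_range}, and propagates annotations to all ancestors.
#'
#' @param n_terms number of terms (>= 1; term 1 is the root).
#' @param genes gene universe to annotate from.
#' @param term_size_range integer range of leaf annotation sizes.
#' @param depth number of levels below the root.
#' @param seed integer seed.
#' @return a \code{"GOAnnotation"} list: \code{term2gene} (propagated,
#'   named list), \code{dag} (child/parent character matrix),
#'   \code{term_name} (named character), \code{root}.
#' @export
generateGO <- function(n_terms, genes, term_size_range = c(5L, 20L),
                       depth = 3L, seed = 1L) {
  if (n_terms < 1L) stop("need at least one term")
  if (max(term_size_range) > length(genes))
    stop("term sizes cannot exceed the gene universe")
  set.seed(as.integer(seed))
  terms <- sprintf("T%04d", seq_len(n_terms))
  level <- c(0L, if (n_terms > 1L)
    sort(sample(seq_len(max(1L, depth)), n_terms - 1L, replace = TRUE)))
  dag <- NULL
  for (i in seq_len(n_terms)[-1]) {
    cand <- terms[level < level[i]]
    np <- min(length(cand), sample(1:2, 1L))
    dag <- rbind(dag, cbind(terms[i], sample(cand, np)))
  }
  if (is.null(dag)) dag <- matrix(character(), 0L, 2L)
  colnames(dag) <- c("child", "parent")
  leaves <- setdiff(terms, dag[, "parent"])
  if (!length(leaves)) leaves <- terms[1L]
  ann <- lapply(leaves, function(tt) {
    k <- sample(seq(term_size_range[1L], term_size_range[2L]), 1L)
    sort(sample(genes, k))
  })
  names(ann) <- leaves
  makeGOAnnotation(ann, dag,
                   term_name = stats::setNames(paste("synthetic process",
                                                     seq_along(terms)),
                                               terms))
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running \code{\link{generatePIN}},
#' \code{\link{generateTargetMap}} and \code{\link{generateExpression}}, plus
#' optional GO and survival fixtures, under a single seed.
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @param go logical; also generate a toy GO annotation over the gene
#'   universe (150 terms, sizes 5-20, depth 3).
#' @param survival logical; also generate a 62-subject survival table
#'   (hazard ratio 2.5, baseline 0.02/month, censoring 0.01/month).
#' @return list: pin, targets, mirna, mrna, truth, and optionally go and
#'   survival.
#' @export
simulateStudy <- function(cfg, go = TRUE, survival = TRUE) {
  pin <- generatePIN(cfg)
  targets <- generateTargetMap(cfg, pin)
  ex <- generateExpression(cfg, pin, targets)
  out <- list(pin = pin, targets = targets, mirna = ex$mirna,
              mrna = ex$mrna, truth = ex$truth)
  if (go)
    out$go <- generateGO(150L, networkNodes(pin), c(5L, 20L), 3L,
                         seed = cfg$seed + 3L)
  if (survival)
    out$survival <- generateSurvival(62L, 2.5, 0.02, 0.01,
                                     seed = cfg$seed + 4L)
  out
}
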