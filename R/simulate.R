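## Seeded synthetic-data generators.  Each generator is a pure function of
## its configuration (seed included): fixed seed, byte-identical output.
## They emulate the statistical structure the classifier assumes —
## significant SNPs and enriched interactions concentrated near planted
## risk genes, class-informative node features with assortative edges, and
## expression matrices with a planted fraction of group-specific genes —
## without claiming to match real genotype or omics distributions.

#' Simulate GWAS-style SNP inputs with planted risk genes
#'
#' Tiles `n_genes` genes along one synthetic chromosome, places `n_snps`
#' SNPs uniformly, and plants the signal: SNPs within 1 kb of a risk gene
#' draw their p-value log-uniformly from `significant_p_range`, all other
#' SNPs uniformly from (1e-6, 1).  Random SNP pairs receive interaction
#' p-values, divided by `interaction_enrichment` when both SNPs are
#' adjacent (within 1 kb) to risk genes.
#'
#' @param n_snps Number of SNPs (`>= n_genes`).
#' @param n_genes Number of genes tiled on the chromosome.
#' @param chrom_length_bp Chromosome length in basepairs.
#' @param n_risk_genes Number of planted risk genes (ignored when
#'   `risk_gene_ids` is given).
#' @param risk_gene_ids Optional explicit risk gene ids.
#' @param significant_p_range Range the planted significant p-values are
#'   drawn from (default well below genome-wide significance).
#' @param interaction_enrichment Factor (`>= 1`) by which risk-adjacent
#'   interaction p-values are divided.
#' @param n_interactions Number of SNP-pair interactions drawn.
#' @param seed Integer seed.
#' @return List with `snps`, `genes`, `interactions` (data frames in the
#'   formats the graph builder reads) and `truth` (risk gene ids, per-SNP
#'   risk adjacency, configuration).
#' @export
simulate_snp_inputs <- function(n_snps = 400L, n_genes = 40L,
                                chrom_length_bp = 40e6,
                                n_risk_genes = 5L, risk_gene_ids = NULL,
                                significant_p_range = c(1e-12, 1e-9),
                                interaction_enrichment = 100,
                                n_interactions = 2000L, seed = 0L) {
  stopifnot(n_snps >= n_genes, interaction_enrichment >= 1,
            significant_p_range[1] > 0,
            significant_p_range[1] <= significant_p_range[2])
  gene_len <- 2e4
  pitch <- floor(chrom_length_bp / n_genes)
  if (pitch <= gene_len)
    stop("chromosome too short to tile ", n_genes, " genes without overlap")
  set.seed(seed)
  gene_id <- sprintf("G%04d", seq_len(n_genes))
  start <- (seq_len(n_genes) - 1L) * pitch + floor(pitch / 4)
  genes <- data.frame(gene_id = gene_id, chrom = "chrS",
                      start = start, end = start + gene_len,
                      stringsAsFactors = FALSE)
  if (is.null(risk_gene_ids))
    risk_gene_ids <- sort(sample(gene_id, n_risk_genes))
  stopifnot(all(risk_gene_ids %in% gene_id))

  snp_id <- sprintf("rs%05d", seq_len(n_snps))
  pos <- sort(sample.int(chrom_length_bp, n_snps))
  # place one guaranteed SNP inside each risk gene so every planted gene
  # has a sub-threshold SNP within any window >= 0
  ridx <- match(risk_gene_ids, gene_id)
  anchor <- sample.int(n_snps, length(ridx))
  pos[anchor] <- genes$start[ridx] + floor(gene_len / 2)
  near_risk <- rep(FALSE, n_snps)
  for (i in ridx)
    near_risk <- near_risk |
      snp_gene_distance(pos, genes$start[i], genes$end[i]) <= 1000
  lo <- log(significant_p_range[1]); hi <- log(significant_p_range[2])
  p_value <- exp(stats::runif(n_snps, log(1e-6), 0))
  p_value[near_risk] <- exp(stats::runif(sum(near_risk), lo, hi))
  snps <- data.frame(snp_id = snp_id, chrom = "chrS", pos = pos,
                     p_value = p_value, stringsAsFactors = FALSE)

  pair <- matrix(sample.int(n_snps, 2L * n_interactions, replace = TRUE),
                 ncol = 2L)
  pair <- pair[pair[, 1L] != pair[, 2L], , drop = FALSE]
  a <- snp_id[pmin(pair[, 1L], pair[, 2L])]
  b <- snp_id[pmax(pair[, 1L], pair[, 2L])]
  dup <- duplicated(paste(a, b))
  a <- a[!dup]; b <- b[!dup]
  p_int <- stats::runif(length(a))
  both_risk <- near_risk[match(a, snp_id)] & near_risk[match(b, snp_id)]
  p_int[both_risk] <- p_int[both_risk] / interaction_enrichment
  interactions <- data.frame(snp_a = a, snp_b = b, p_interaction = p_int,
                             stringsAsFactors = FALSE)

  list(snps = snps, genes = genes, interactions = interactions,
       truth = list(risk_genes = risk_gene_ids, snp_near_risk = near_risk,
                    config = list(n_snps = n_snps, n_genes = n_genes,
                                  chrom_length_bp = chrom_length_bp,
                                  significant_p_range = significant_p_range,
                                  interaction_enrichment =
                                    interaction_enrichment,
                                  seed = seed)))
}

#' Simulate a labeled gene graph with controllable signal
#'
#' Node classes are drawn with probability `pos_fraction`; features are
#' unit-variance Gaussians with the positive-class mean shifted by
#' `class_separation` on a random half of the features; edges are drawn
#' pairwise so that a within-class pair is `homophily / (1 - homophily)`
#' times as likely as a between-class pair while the overall density stays
#' at `edge_density`; `label_fraction` of the nodes keep their labels, the
#' rest are unlabeled context.  Edge weights mimic `-log10` interaction
#' p-values.
#'
#' @param n_genes Number of nodes (default 500).
#' @param n_features Feature dimension (default 20).
#' @param pos_fraction Expected positive-class fraction (default 0.15).
#' @param class_separation Mean shift in SD units on informative features
#'   (default 1.5).
#' @param homophily Probability weight of within-class edges in `[0, 1)`
#'   relative tilt (0.5 = no assortativity; default 0.8).
#' @param edge_density Expected fraction of node pairs joined by an edge
#'   (default 0.02).
#' @param label_fraction Fraction of nodes carrying labels (default 0.6).
#' @param seed Integer seed.
#' @return A [gene_graph] (masks all `none`; see [set_mask()]) with the
#'   complete truth in attributes: `true_labels` (all nodes) and
#'   `informative_features`.
#' @export
simulate_gene_graph <- function(n_genes = 500L, n_features = 20L,
                                pos_fraction = 0.15, class_separation = 1.5,
                                homophily = 0.8, edge_density = 0.02,
                                label_fraction = 0.6, seed = 0L) {
  stopifnot(n_genes >= 20L, pos_fraction > 0, pos_fraction < 1,
            homophily >= 0, homophily < 1, edge_density > 0,
            edge_density <= 1, label_fraction > 0, label_fraction <= 1)
  set.seed(seed)
  ids <- sprintf("N%04d", seq_len(n_genes))
  y <- stats::rbinom(n_genes, 1L, pos_fraction)
  if (sum(y) < 2L) y[sample.int(n_genes, 2L)] <- 1L
  X <- matrix(stats::rnorm(n_genes * n_features), n_genes, n_features,
              dimnames = list(ids, sprintf("f%02d", seq_len(n_features))))
  info <- sort(sample.int(n_features, max(1L, n_features %/% 2L)))
  X[y == 1L, info] <- X[y == 1L, info] + class_separation

  # pairwise Bernoulli edges with within/between odds r = h/(1-h)
  pr <- utils::combn(n_genes, 2L)
  same <- y[pr[1L, ]] == y[pr[2L, ]]
  r <- if (homophily >= 1) Inf else homophily / (1 - homophily)
  n_pairs <- ncol(pr)
  target <- edge_density * n_pairs
  p_b <- target / (sum(same) * r + sum(!same))
  p_w <- min(r * p_b, 1)
  keep <- stats::runif(n_pairs) < ifelse(same, p_w, p_b)
  ia <- pr[1L, keep]; ib <- pr[2L, keep]
  weight <- -log10(stats::runif(sum(keep), 1e-8, 1e-2))
  edges <- data.frame(gene_a = ids[ia], gene_b = ids[ib], weight = weight,
                      stringsAsFactors = FALSE)

  labeled <- sort(sample.int(n_genes, round(label_fraction * n_genes)))
  labels <- rep(NA_integer_, n_genes)
  names(labels) <- ids
  labels[labeled] <- y[labeled]
  # ensure both classes appear among the labeled nodes
  for (cl in 0:1)
    if (sum(labels == cl, na.rm = TRUE) < 2L) {
      add <- which(y == cl & is.na(labels))
      labels[add[seq_len(min(2L, length(add)))]] <- cl
    }

  mask <- rep("none", n_genes); names(mask) <- ids
  g <- structure(list(node_ids = ids, features = X, features_raw = X,
                      edges = edges, labels = labels, mask = mask,
                      preprocess = NULL),
                 class = "gene_graph")
  attr(g, "true_labels") <- stats::setNames(y, ids)
  attr(g, "informative_features") <- info
  g
}

#' Simulate expression with planted group-specific genes
#'
#' Baseline log-normal expression with per-gene base level; a
#' `specific_fraction` of genes is assigned one group where the mean is
#' multiplied by `fold_change`; log-scale Gaussian noise with SD
#' `noise_sd` is added everywhere.
#'
#' @param n_genes Number of genes (default 200).
#' @param groups Character vector of group (tissue / cell-type) labels.
#' @param samples_per_group Samples per group (default 10).
#' @param specific_fraction Fraction of genes planted as group-specific
#'   (default 0.1).
#' @param fold_change Mean multiplier in the assigned group (`> 1` plants
#'   a real effect; `1` is the null; default 8).
#' @param noise_sd Log-scale noise SD (default 0.2).
#' @param seed Integer seed.
#' @return List: `values` (genes x samples matrix), `sample_group`,
#'   and `planted` (named character vector gene -> assigned group).
#' @export
simulate_expression <- function(n_genes = 200L,
                                groups = c("neuron", "astrocyte",
                                           "oligodendrocyte", "microglia"),
                                samples_per_group = 10L,
                                specific_fraction = 0.1, fold_change = 8,
                                noise_sd = 0.2, seed = 0L) {
  stopifnot(specific_fraction > 0, specific_fraction < 1, fold_change >= 1,
            noise_sd >= 0, length(groups) >= 2L)
  set.seed(seed)
  ids <- sprintf("E%04d", seq_len(n_genes))
  sample_group <- rep(groups, each = samples_per_group)
  n_s <- length(sample_group)
  base <- exp(stats::rnorm(n_genes, log(5), 0.5))
  logmu <- matrix(log(base), n_genes, n_s)
  n_spec <- max(1L, round(specific_fraction * n_genes))
  spec_genes <- sort(sample.int(n_genes, n_spec))
  spec_group <- sample(groups, n_spec, replace = TRUE)
  for (k in seq_len(n_spec))
    logmu[spec_genes[k], sample_group == spec_group[k]] <-
      logmu[spec_genes[k], sample_group == spec_group[k]] + log(fold_change)
  values <- exp(logmu + stats::rnorm(n_genes * n_s, 0, noise_sd))
  dimnames(values) <- list(ids, sprintf("%s_s%02d", sample_group,
                                        stats::ave(seq_len(n_s),
                                                   sample_group,
                                                   FUN = seq_along)))
  list(values = values, sample_group = sample_group,
       planted = stats::setNames(spec_group, ids[spec_genes]))
}
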