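test_that("generators are pure functions of their configuration", {
  s1 <- simulate_snp_inputs(seed = 5)
  s2 <- simulate_snp_inputs(seed = 5)
  expect_identical(s1, s2)
  g1 <- simulate_gene_graph(n_genes = 60, seed = 5)
  g2 <- simulate_gene_graph(n_genes = 60, seed = 5)
  expect_identical(g1, g2)
  e1 <- simulate_expression(seed = 5)
  e2 <- simulate_expression(seed = 5)
  expect_identical(e1, e2)
  expect_false(identical(simulate_snp_inputs(seed = 6)$snps$p_value,
                         s1$snps$p_value))
})

test_that("planted risk genes are always recovered as candidates", {
  for (seed in 0:4) {
    sim <- simulate_snp_inputs(seed = seed)
    cand <- select_candidate_genes(sim$snps, sim$genes)
    expect_true(all(sim$truth$risk_genes %in% cand))
  }
})

test_that("candidate and edge construction on the fixture matches the brute-force oracles", {
  sim <- simulate_snp_inputs(n_snps = 80, n_genes = 12,
                             chrom_length_bp = 6e6, n_interactions = 300,
                             seed = 11)
  expect_identical(select_candidate_genes(sim$snps, sim$genes),
                   bf_candidates(sim$snps, sim$genes, 5e-8, 1e6))
  m <- map_snps_to_genes(sim$snps, sim$genes, 1000)
  bm <- bf_snp_map(sim$snps, sim$genes, 1000)
  expect_identical(sort_map(m), sort_map(bm))
  e <- suppressMessages(build_gene_edges(sim$interactions, m))
  be <- bf_edges(sim$interactions, m)
  expect_equal(e[c("gene_a", "gene_b", "weight")], be, ignore_attr = TRUE)
})

test_that("simulated graphs respect density, labeling, and class structure", {
  g <- simulate_gene_graph(seed = 0)
  n <- length(g$node_ids)
  target <- 0.02 * n * (n - 1) / 2
  expect_lt(abs(nrow(g$edges) - target) / target, 0.10)
  expect_equal(sum(!is.na(g$labels)), round(0.6 * n))
  y <- attr(g, "true_labels")
  expect_true(all(g$labels[!is.na(g$labels)] ==
                    y[names(g$labels)[!is.na(g$labels)]]))
  # informative features separate the classes by construction
  info <- attr(g, "informative_features")
  gap <- colMeans(g$features[y == 1, info, drop = FALSE]) -
    colMeans(g$features[y == 0, info, drop = FALSE])
  expect_true(all(gap > 0.5))
  # homophily: within-class edges over-represented
  ia <- match(g$edges$gene_a, g$node_ids)
  ib <- match(g$edges$gene_b, g$node_ids)
  same <- mean(y[ia] == y[ib])
  base <- mean(outer(y, y, "==")[upper.tri(diag(n))])
  expect_gt(same, base + 0.1)
})

test_that("null interaction enrichment leaves risk and non-risk edge weights exchangeable", {
  w_risk <- c(); w_other <- c()
  for (seed in 1:15) {
    sim <- simulate_snp_inputs(interaction_enrichment = 1, seed = seed,
                               n_interactions = 600)
    near <- sim$truth$snp_near_risk
    both <- near[match(sim$interactions$snp_a, sim$snps$snp_id)] &
      near[match(sim$interactions$snp_b, sim$snps$snp_id)]
    w <- -log10(sim$interactions$p_interaction)
    w_risk <- c(w_risk, w[both])
    w_other <- c(w_other, w[!both])
  }
  expect_gt(wilcox.test(w_risk, w_other)$p.value, 0.01)
})

test_that("expression simulation has the requested shape and null behavior", {
  sim <- simulate_expression(n_genes = 50, groups = c("a", "b", "c"),
                             samples_per_group = 4, seed = 2)
  expect_equal(dim(sim$values), c(50L, 12L))
  expect_true(all(sim$values > 0))
  expect_equal(table(sim$sample_group), table(rep(c("a", "b", "c"), 4)),
               ignore_attr = TRUE)
  # fold_change = 1: planted genes indistinguishable from the rest
  null <- simulate_expression(n_genes = 150, fold_change = 1, seed = 3)
  ts <- tissue_specificity_scores(null$values, null$sample_group)
  s_planted <- mapply(function(g, grp) ts[g, grp],
                      names(null$planted), null$planted)
  others <- setdiff(rownames(ts), names(null$planted))
  set.seed(30)
  s_other <- mapply(function(g, grp) ts[g, grp], others,
                    sample(colnames(ts), length(others), replace = TRUE))
  expect_gt(wilcox.test(s_planted, s_other)$p.value, 0.01)
})

test_that("fixtures round-trip losslessly through the file writers and readers", {
  tmp <- withr::local_tempdir()
  sim <- simulate_snp_inputs(n_snps = 60, n_genes = 10,
                             chrom_length_bp = 5e6, seed = 4)
  gw <- file.path(tmp, "gwas.tsv")
  write.table(data.frame(SNP = sim$snps$snp_id, CHR = sim$snps$chrom,
                         BP = sim$snps$pos, P = sim$snps$p_value),
              gw, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_gwas_tsv(gw), sim$snps, ignore_attr = TRUE)

  bed <- file.path(tmp, "genes.bed")
  write.table(sim$genes[c("chrom", "start", "end", "gene_id")], bed,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_equal(read_gene_bed(bed), sim$genes[names(read_gene_bed(bed))],
               ignore_attr = TRUE)

  itsv <- file.path(tmp, "inter.tsv")
  write.table(sim$interactions, itsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_equal(read_interactions_tsv(itsv), sim$interactions,
               ignore_attr = TRUE)

  edges <- data.frame(gene_a = c("g1", "g2"), gene_b = c("g3", "g4"),
                      weight = c(1.234567891, 8.5))
  ep <- file.path(tmp, "edges.tsv")
  write_edges_tsv(edges, ep)
  back <- read.delim(ep)
  expect_equal(back$weight, round(edges$weight, 6))
})
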