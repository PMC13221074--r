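test_that("candidate gene selection honors threshold, chromosome and inclusive window", {
  genes <- data.frame(gene_id = "GA", chrom = "chr1",
                      start = 5500000L, end = 5600000L)
  snps <- data.frame(snp_id = "rs1", chrom = "chr1", pos = 5000000L,
                     p_value = 1e-9)
  expect_identical(select_candidate_genes(snps, genes), "GA")

  # sub-genome-wide p excluded
  snps$p_value <- 1e-7
  expect_identical(select_candidate_genes(snps, genes), character(0))

  # wrong chromosome excluded
  snps$p_value <- 1e-9; snps$chrom <- "chr2"
  expect_identical(select_candidate_genes(snps, genes), character(0))

  # distance exactly at the window boundary is included (gene body starts
  # 0-based 2,000,000 -> first base 2,000,001; SNP at 1,000,001)
  genes2 <- data.frame(gene_id = "GB", chrom = "chr1",
                       start = 2000000L, end = 2100000L)
  snps2 <- data.frame(snp_id = "rs2", chrom = "chr1", pos = 1000001L,
                      p_value = 1e-9)
  expect_identical(select_candidate_genes(snps2, genes2), "GB")
  expect_identical(bf_candidates(snps2, genes2, 5e-8, 1e6), "GB")
  snps2$pos <- 1000000L
  expect_identical(select_candidate_genes(snps2, genes2), character(0))

  expect_warning(select_candidate_genes(snps, genes[0, ]), "empty gene")
  expect_error(select_candidate_genes(
    data.frame(snp_id = "a", chrom = "chr1", pos = -5, p_value = 0.1),
    genes), "positions")
})

test_that("SNP-to-gene mapping assigns within the inclusive window, possibly to several genes", {
  genes <- data.frame(gene_id = c("G1", "G2"), chrom = "chr1",
                      start = c(10000L, 21000L), end = c(20000L, 30000L))
  snps <- data.frame(snp_id = c("in_body", "far", "between"),
                     chrom = "chr1", pos = c(15000L, 8499L, 20500L),
                     p_value = 0.5)
  m <- map_snps_to_genes(snps, genes, window_bp = 1000)
  expect_setequal(m$G1, c("in_body", "between"))
  expect_identical(m$G2, "between")    # within 1 kb of both
  expect_false("far" %in% unlist(m))   # 1,501 bp upstream of G1
})

test_that("gene edges take the max -log10 p over connecting interactions, no self-edges", {
  snp_map <- list(g1 = c("s1", "s2"), g2 = c("s3", "s4"), g3 = "s5")
  inter <- data.frame(snp_a = c("s1", "s2", "s1", "s2"),
                      snp_b = c("s3", "s4", "s2", "s9"),
                      p_interaction = c(1e-6, 1e-10, 1e-4, 1e-3))
  e <- suppressMessages(build_gene_edges(inter, snp_map))
  # s1-s2 joins g1 to itself only -> dropped; s2-s9 unmapped -> skipped
  expect_identical(e$gene_a, "g1")
  expect_identical(e$gene_b, "g2")
  expect_equal(e$weight, 10)
  expect_identical(attr(e, "n_skipped"), 1L)
  # no interaction joining g3 -> no edge with g3
  expect_false("g3" %in% c(e$gene_a, e$gene_b))
})

test_that("graph-build operations agree with brute-force oracles on random instances", {
  for (seed in 1:25) {
    inst <- rand_snp_instance(seed)
    expect_identical(select_candidate_genes(inst$snps, inst$genes),
                     bf_candidates(inst$snps, inst$genes, 5e-8, 1e6))
    m <- map_snps_to_genes(inst$snps, inst$genes, 5000)
    bm <- bf_snp_map(inst$snps, inst$genes, 5000)
    expect_identical(sort_map(m), sort_map(bm))
  }
})

test_that("top-fraction filter keeps the largest weights with deterministic tie-breaking", {
  set.seed(7)
  e200 <- data.frame(gene_a = sprintf("a%03d", 1:200),
                     gene_b = sprintf("b%03d", 1:200),
                     weight = runif(200, 0, 12))
  top <- filter_top_fraction(e200, 0.01)
  expect_equal(nrow(top), 2L)
  expect_setequal(top$weight, sort(e200$weight, decreasing = TRUE)[1:2])
  expect_equal(filter_top_fraction(e200, 1.0)[order(e200$gene_a), ],
               e200[order(e200$gene_a), ], ignore_attr = TRUE)

  # 5 edges tied at the cutoff weight, only 3 slots
  tied <- data.frame(gene_a = sprintf("g%02d", 1:100),
                     gene_b = sprintf("h%02d", 1:100),
                     weight = c(rep(5, 5), runif(95, 0, 4)))
  out <- filter_top_fraction(tied, 0.03)
  expect_equal(nrow(out), 3L)
  expect_equal(out, bf_top_fraction(tied, 0.03))
  expect_true(min(out$weight) >= max(setdiff(tied$weight, out$weight)))
  expect_error(filter_top_fraction(tied, 0), "fraction")
  expect_error(filter_top_fraction(tied, 1.5), "fraction")
})

test_that("negative set excludes positives and their interaction partners", {
  low <- c("n1", "n2", "n3", "p1")
  pos <- c("p1", "p2")
  pairs <- data.frame(a = c("n2", "x1"), b = c("p2", "n3"))
  expect_identical(derive_negative_set(low, pos, pairs), c("n1", "n3"))
  expect_identical(derive_negative_set(low, pos, pairs[0, ]),
                   c("n1", "n2", "n3"))
  expect_identical(derive_negative_set(low, pos), c("n1", "n2", "n3"))
})

make_omics <- function() {
  data.frame(gene_id = c("gA", "gB", "gC", "gD", "gE"),
             f1 = c(1, 2, 3, NA, 10),
             f2 = c(0.5, 0.9, 0.7, 0.7, 0.1))
}

test_that("graph assembly z-scores and imputes using train-mask nodes only", {
  labs <- label_set(c("gA"), c("gB", "gC", "gD"))
  masks <- c(gA = "train", gB = "train", gC = "train", gD = "val")
  g <- assemble_graph(c("gA", "gB", "gC", "gD", "gE"), labs,
                      data.frame(gene_a = "gA", gene_b = "gE", weight = 3),
                      make_omics(), masks)
  tr <- which(g$mask == "train")
  expect_equal(colMeans(g$features[tr, ]), c(f1 = 0, f2 = 0),
               tolerance = 1e-9)
  # missing f1 for gD imputed with the train median (2), then z-scored
  expect_equal(g$features["gD", "f1"],
               (2 - mean(c(1, 2, 3))) / sd(c(1, 2, 3)))
  # f2 train median is 0.7; gD raw 0.7 present already
  expect_equal(g$preprocess$median[2], 0.7, ignore_attr = TRUE)
  # isolated node retained
  expect_true("gB" %in% g$node_ids)
  expect_identical(unname(g$labels["gA"]), 1L)
})

test_that("preprocessing parameters are a pure function of train rows (no leakage)", {
  labs <- label_set(c("gA"), c("gB", "gC", "gD"))
  masks <- c(gA = "train", gB = "train", gC = "train", gD = "val")
  om1 <- make_omics()
  om2 <- om1
  om2[om2$gene_id == "gD", c("f1", "f2")] <- c(99, -99)  # val node only
  edges <- data.frame(gene_a = "gA", gene_b = "gB", weight = 1)
  cand <- c("gA", "gB", "gC", "gD", "gE")
  g1 <- assemble_graph(cand, labs, edges, om1, masks)
  g2 <- assemble_graph(cand, labs, edges, om2, masks)
  expect_identical(g1$preprocess, g2$preprocess)
  # train and unlabeled rows unaffected by the val-row change
  expect_identical(g1$features[c("gA", "gB", "gC", "gE"), ],
                   g2$features[c("gA", "gB", "gC", "gE"), ])
  # assembly is deterministic: repeated runs byte-identical
  g3 <- assemble_graph(cand, labs, edges, om1, masks)
  expect_identical(g1$features, g3$features)
})

test_that("degenerate feature columns are handled with warnings", {
  labs <- label_set("gA", c("gB", "gC"))
  masks <- c(gA = "train", gB = "train", gC = "val")
  om <- data.frame(gene_id = c("gA", "gB", "gC"),
                   f1 = c(5, 5, 7), f2 = c(NA, NA, NA))
  w <- capture_warnings(
    g <- assemble_graph(c("gA", "gB", "gC"), labs,
                        data.frame(gene_a = character(0),
                                   gene_b = character(0),
                                   weight = numeric(0)), om, masks))
  expect_true(any(grepl("constant", w)))
  expect_true(all(is.finite(g$features)))
})
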