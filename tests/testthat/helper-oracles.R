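# Independent brute-force oracles and small random-instance generators.
# These deliberately re-derive every quantity with naive O(n^2) loops or
# exhaustive enumeration, sharing no code with the package internals.

sort_map <- function(m) if (length(m)) m[order(names(m))] else m

bf_snp_gene_dist <- function(pos, start0, end0) {
  first <- start0 + 1  # 1-based first base of the gene body
  if (pos < first) first - pos
  else if (pos > end0) pos - end0
  else 0
}

bf_candidates <- function(snps, genes, p_thr, window) {
  out <- character(0)
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(snps))) {
      if (snps$p_value[j] >= p_thr) next
      if (snps$chrom[j] != genes$chrom[i]) next
      d <- bf_snp_gene_dist(snps$pos[j], genes$start[i], genes$end[i])
      if (d <= window) { out <- c(out, genes$gene_id[i]); break }
    }
  }
  sort(unique(out))
}

bf_snp_map <- function(snps, genes, window) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    hits <- character(0)
    for (j in seq_len(nrow(snps))) {
      if (snps$chrom[j] != genes$chrom[i]) next
      if (bf_snp_gene_dist(snps$pos[j], genes$start[i],
                           genes$end[i]) <= window)
        hits <- c(hits, snps$snp_id[j])
    }
    if (length(hits)) out[[genes$gene_id[i]]] <- hits
  }
  out
}

bf_edges <- function(interactions, snp_map) {
  gene_ids <- names(snp_map)
  ga <- gb <- character(0); w <- numeric(0)
  if (length(gene_ids) >= 2L) {
    for (i in seq_len(length(gene_ids) - 1L)) {
      for (j in (i + 1L):length(gene_ids)) {
        g1 <- gene_ids[i]; g2 <- gene_ids[j]
        best <- -Inf
        for (k in seq_len(nrow(interactions))) {
          sa <- interactions$snp_a[k]; sb <- interactions$snp_b[k]
          ok <- (sa %in% snp_map[[g1]] && sb %in% snp_map[[g2]]) ||
            (sb %in% snp_map[[g1]] && sa %in% snp_map[[g2]])
          if (ok) best <- max(best, -log10(interactions$p_interaction[k]))
        }
        if (is.finite(best)) {
          pair <- sort(c(g1, g2))
          ga <- c(ga, pair[1]); gb <- c(gb, pair[2]); w <- c(w, best)
        }
      }
    }
  }
  df <- data.frame(gene_a = ga, gene_b = gb, weight = w,
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

bf_top_fraction <- function(edges, fraction) {
  n_keep <- max(1L, floor(fraction * nrow(edges)))
  ord <- order(-edges$weight, edges$gene_a, edges$gene_b)
  out <- edges[sort(ord[seq_len(n_keep)]), , drop = FALSE]
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

bf_youden <- function(scores, labels) {
  best_t <- NA; best_j <- -Inf; best_sens <- -Inf
  for (t in sort(unique(scores))) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    j <- sens + spec - 1
    better <- j > best_j + 1e-12 ||
      (abs(j - best_j) <= 1e-12 && sens > best_sens + 1e-12) ||
      (abs(j - best_j) <= 1e-12 && abs(sens - best_sens) <= 1e-12 &&
         t < best_t)
    if (better) { best_t <- t; best_j <- j; best_sens <- sens }
  }
  best_t
}

# exhaustive one-sided ("x greater") rank-sum p by enumerating every
# assignment of the pooled values to the two groups (tie-free inputs)
bf_wilcox_greater <- function(x, y) {
  pool <- c(x, y)
  n <- length(pool); m <- length(x)
  r <- rank(pool)
  w_obs <- sum(r[seq_len(m)])
  combos <- utils::combn(n, m)
  w_all <- apply(combos, 2L, function(ii) sum(r[ii]))
  mean(w_all >= w_obs - 1e-9)
}

# hypergeometric tail for a 2x2 enrichment table
bf_fisher_greater <- function(a, b, cc, d) {
  N <- a + b + cc + d
  K <- a + cc   # annotated
  n <- a + b    # query size
  ks <- max(0, n + K - N):min(K, n)
  sum(stats::dhyper(ks[ks >= a], K, N - K, n))
}

rand_snp_instance <- function(seed) {
  set.seed(seed)
  n_s <- sample(20:200, 1)
  n_g <- sample(5:50, 1)
  snps <- data.frame(
    snp_id = sprintf("s%03d", seq_len(n_s)),
    chrom = sample(c("chr1", "chr2"), n_s, replace = TRUE),
    pos = sample.int(5e6, n_s), p_value = 10^stats::runif(n_s, -12, 0),
    stringsAsFactors = FALSE)
  start <- sample.int(5e6, n_g)
  genes <- data.frame(
    gene_id = sprintf("g%02d", seq_len(n_g)),
    chrom = sample(c("chr1", "chr2"), n_g, replace = TRUE),
    start = start, end = start + sample.int(5e4, n_g),
    stringsAsFactors = FALSE)
  list(snps = snps, genes = genes)
}

# a small graph with train/val/test masks, for fast model tests
toy_graph <- function(seed = 0, n = 120, sep = 2, density = 0.05) {
  g <- simulate_gene_graph(n_genes = n, n_features = 8,
                           class_separation = sep, edge_density = density,
                           seed = seed)
  sp <- stratified_holdout(g$labels, 0.8, seed = seed)
  folds <- kfold_assign(sp$train, g$labels, k = 4, seed = seed)
  val <- sp$train[folds == 1]
  set_mask(g, train = setdiff(sp$train, val), val = val, test = sp$test)
}

fast_train_cfg <- function(seed = 0, epochs = 15)
  pgt_train_config(max_epochs = epochs, patience = epochs, seed = seed)

small_model_cfg <- function(...)
  pgt_model_config(hidden_dim = 16, n_heads = 2, prototypes_per_class = 3,
                   ...)
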