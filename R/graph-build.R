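## Gene-graph construction from GWAS summary statistics, gene coordinates,
## SNP-SNP interaction lists, omics tables, and curated label lists.
##
## Coordinate conventions: SNP positions are 1-based; gene intervals are
## BED-style 0-based half-open and converted to 1-based inclusive bodies
## internally.  All SNP-gene distances are measured from the SNP position to
## the nearest gene-body coordinate (0 inside the body) and windows are
## inclusive.

validate_snps <- function(snps) {
  need <- c("snp_id", "chrom", "pos", "p_value")
  if (!is.data.frame(snps) || !all(need %in% names(snps)))
    stop("`snps` must be a data frame with columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(snps$snp_id))
    stop("duplicate snp_id in SNP table")
  if (any(!is.finite(snps$pos)) || any(snps$pos < 1))
    stop("SNP positions must be integers >= 1")
  if (any(!is.finite(snps$p_value)) || any(snps$p_value <= 0) ||
      any(snps$p_value > 1))
    stop("SNP p-values must lie in (0, 1]")
  snps
}

validate_genes <- function(genes) {
  need <- c("gene_id", "chrom", "start", "end")
  if (!is.data.frame(genes) || !all(need %in% names(genes)))
    stop("`genes` must be a data frame with columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in gene table")
  if (any(!is.finite(genes$start)) || any(!is.finite(genes$end)) ||
      any(genes$start < 0) || any(genes$start >= genes$end))
    stop("gene intervals must satisfy 0 <= start < end (BED half-open)")
  genes
}

# distance (bp) from each SNP position to the gene body [start+1, end]
# (1-based inclusive); 0 when the SNP falls inside the body
snp_gene_distance <- function(pos, start0, end0) {
  pmax(0, (start0 + 1) - pos, pos - end0)
}

#' Select candidate genes near genome-wide-significant SNPs
#'
#' A gene is a candidate when its gene body lies within `window_bp`
#' (inclusive) of at least one SNP with `p_value < p_threshold` on the same
#' chromosome.  Distance is measured from the SNP position to the nearest
#' gene-body coordinate, so a SNP inside the gene has distance 0.
#'
#' @param snps Data frame with columns `snp_id`, `chrom`, `pos` (1-based),
#'   `p_value`.
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (BED 0-based half-open).
#' @param p_threshold Genome-wide significance threshold (default 5e-8).
#' @param window_bp Window radius in basepairs (default 1 Mb).
#' @return Character vector of candidate gene ids (sorted, unique).
#' @export
select_candidate_genes <- function(snps, genes, p_threshold = 5e-8,
                                   window_bp = 1e6) {
  snps <- validate_snps(snps)
  genes <- validate_genes(genes)
  stopifnot(window_bp > 0, p_threshold > 0)
  if (nrow(genes) == 0L) {
    warning("empty gene list; no candidate genes")
    return(character(0))
  }
  idx <- snps$p_value < p_threshold
  if (!any(idx)) return(character(0))
  sig <- snps[idx, , drop = FALSE]
  hit <- logical(nrow(genes))
  for (ch in unique(sig$chrom)) {
    g <- which(genes$chrom == ch & !hit)
    if (!length(g)) next
    s <- sig[sig$chrom == ch, , drop = FALSE]
    for (i in g) {
      d <- snp_gene_distance(s$pos, genes$start[i], genes$end[i])
      if (any(d <= window_bp)) hit[i] <- TRUE
    }
  }
  sort(unique(genes$gene_id[hit]))
}

#' Map SNPs to nearby genes
#'
#' Assigns each SNP to every gene whose body lies within `window_bp`
#' (inclusive) of the SNP position on the same chromosome; a SNP may map to
#' several genes and a gene collects several SNPs.
#'
#' @inheritParams select_candidate_genes
#' @param window_bp Assignment window in basepairs (default 1 kb).
#' @return Named list: one character vector of SNP ids per gene id (genes
#'   with no assigned SNP are omitted).
#' @export
map_snps_to_genes <- function(snps, genes, window_bp = 1000) {
  snps <- validate_snps(snps)
  genes <- validate_genes(genes)
  stopifnot(window_bp > 0)
  out <- list()
  for (i in seq_len(nrow(genes))) {
    sel <- snps$chrom == genes$chrom[i] &
      snp_gene_distance(snps$pos, genes$start[i], genes$end[i]) <= window_bp
    if (any(sel)) out[[genes$gene_id[i]]] <- snps$snp_id[sel]
  }
  out
}

canonical_pairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  list(a = a, b = b)
}

#' Aggregate SNP-SNP interactions into gene-gene edges
#'
#' For every unordered gene pair joined by at least one SNP-SNP interaction
#' (one SNP mapped to each gene) an edge is emitted whose weight is the
#' maximum `-log10(p_interaction)` over all such interactions.  Self-edges
#' are never produced; interactions touching an unmapped SNP are skipped and
#' counted in the `n_skipped` attribute.
#'
#' @param interactions Data frame with columns `snp_a`, `snp_b`,
#'   `p_interaction` in (0, 1].
#' @param snp_gene_map Named list from [map_snps_to_genes()].
#' @return Data frame with columns `gene_a`, `gene_b` (canonical order:
#'   `gene_a < gene_b`), `weight`; attribute `n_skipped` counts interactions
#'   dropped because a SNP was unmapped.
#' @export
build_gene_edges <- function(interactions, snp_gene_map) {
  need <- c("snp_a", "snp_b", "p_interaction")
  if (!is.data.frame(interactions) || !all(need %in% names(interactions)))
    stop("`interactions` must have columns ", paste(need, collapse = ", "))
  if (any(interactions$p_interaction <= 0 | interactions$p_interaction > 1))
    stop("interaction p-values must lie in (0, 1]")
  if (any(interactions$snp_a == interactions$snp_b))
    stop("self-interactions (snp_a == snp_b) are not allowed")
  snp2gene <- list()
  for (g in names(snp_gene_map))
    for (s in snp_gene_map[[g]])
      snp2gene[[s]] <- c(snp2gene[[s]], g)

  ga <- character(0); gb <- character(0); w <- numeric(0)
  n_skipped <- 0L
  for (k in seq_len(nrow(interactions))) {
    gsa <- snp2gene[[interactions$snp_a[k]]]
    gsb <- snp2gene[[interactions$snp_b[k]]]
    if (is.null(gsa) || is.null(gsb)) { n_skipped <- n_skipped + 1L; next }
    pr <- expand.grid(a = gsa, b = gsb, stringsAsFactors = FALSE)
    pr <- pr[pr$a != pr$b, , drop = FALSE]
    if (!nrow(pr)) next
    cp <- canonical_pairs(pr$a, pr$b)
    ga <- c(ga, cp$a); gb <- c(gb, cp$b)
    w <- c(w, rep(-log10(interactions$p_interaction[k]), nrow(pr)))
  }
  if (!length(ga)) {
    edges <- data.frame(gene_a = character(0), gene_b = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  } else {
    key <- paste(ga, gb, sep = "\r")
    agg <- tapply(w, key, max)
    parts <- strsplit(names(agg), "\r", fixed = TRUE)
    edges <- data.frame(gene_a = vapply(parts, `[`, "", 1L),
                        gene_b = vapply(parts, `[`, "", 2L),
                        weight = as.numeric(agg), stringsAsFactors = FALSE)
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  if (n_skipped > 0L)
    message(n_skipped, " interaction(s) skipped: SNP not mapped to any gene")
  attr(edges, "n_skipped") <- n_skipped
  edges
}

#' Keep the strongest fraction of gene-gene edges
#'
#' Retains the `max(1, floor(fraction * nrow(edges)))` edges with the
#' largest weights.  Ties at the cutoff are broken deterministically by the
#' canonical `(gene_a, gene_b)` lexicographic order.
#'
#' @param edges Edge data frame from [build_gene_edges()].
#' @param fraction Fraction in (0, 1] of edges to keep (default 0.01).
#' @return The filtered edge data frame.
#' @export
filter_top_fraction <- function(edges, fraction = 0.01) {
  if (!is.data.frame(edges) ||
      !all(c("gene_a", "gene_b", "weight") %in% names(edges)))
    stop("`edges` must have columns gene_a, gene_b, weight")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("`fraction` must lie in (0, 1]")
  if (nrow(edges) == 0L) stop("`edges` is empty")
  n_keep <- max(1L, floor(fraction * nrow(edges)))
  ord <- order(-edges$weight, edges$gene_a, edges$gene_b)
  out <- edges[ord[seq_len(n_keep)], , drop = FALSE]
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive a negative gene set by interaction exclusion
#'
#' Starting from genes with low expression in the target tissue, removes the
#' positive genes themselves and every gene that shares a protein-interaction
#' pair with a positive gene; the remainder is the negative training set.
#'
#' @param low_expression_genes Character vector of low-expression gene ids.
#' @param positives Character vector of positive (disease) gene ids.
#' @param interaction_pairs Data frame with two character columns naming
#'   interacting gene pairs (unordered; e.g. a BioGRID-style pair list).
#' @return Sorted character vector of negative gene ids.
#' @export
derive_negative_set <- function(low_expression_genes, positives,
                                interaction_pairs = NULL) {
  neg <- setdiff(low_expression_genes, positives)
  if (!is.null(interaction_pairs) && nrow(interaction_pairs)) {
    a <- as.character(interaction_pairs[[1L]])
    b <- as.character(interaction_pairs[[2L]])
    partners <- unique(c(b[a %in% positives], a[b %in% positives]))
    neg <- setdiff(neg, partners)
  }
  sort(unique(neg))
}

#' Construct a label set
#'
#' @param positives,negatives Character vectors of gene ids; must be
#'   disjoint.
#' @return Object of class `label_set` with elements `positives` and
#'   `negatives`.
#' @export
label_set <- function(positives, negatives) {
  positives <- unique(as.character(positives))
  negatives <- unique(as.character(negatives))
  if (length(intersect(positives, negatives)))
    stop("positive and negative gene sets overlap")
  structure(list(positives = positives, negatives = negatives),
            class = "label_set")
}

fit_preprocess <- function(features, train_idx) {
  if (!length(train_idx)) stop("no training nodes to fit preprocessing on")
  d <- ncol(features)
  med <- ctr <- scl <- numeric(d)
  for (j in seq_len(d)) {
    tr <- features[train_idx, j]
    med[j] <- if (all(is.na(tr))) 0 else stats::median(tr, na.rm = TRUE)
    tr[is.na(tr)] <- med[j]
    ctr[j] <- mean(tr)
    s <- stats::sd(tr)
    if (!is.finite(s) || s == 0) {
      warning("feature column ", j, " constant on training nodes; SD set to 1")
      s <- 1
    }
    scl[j] <- s
  }
  list(median = med, center = ctr, scale = scl)
}

apply_preprocess <- function(features, pp) {
  for (j in seq_len(ncol(features))) {
    x <- features[, j]
    x[is.na(x)] <- pp$median[j]
    features[, j] <- (x - pp$center[j]) / pp$scale[j]
  }
  features
}

#' Assemble a labeled gene graph
#'
#' Combines the candidate-gene set, label set, filtered edge list, and one
#' or more omics feature tables into a single graph object.  The node set is
#' the union of candidates and labeled genes; genes absent from the edge
#' list remain as isolated nodes.  Feature columns are concatenated across
#' tables, missing entries are imputed with the per-column median of the
#' train-mask nodes, and every column is z-scored with mean/SD fitted on the
#' train-mask nodes only, so no information leaks from validation or test
#' rows into the preprocessing.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param labels A [label_set()].
#' @param edges Edge data frame (`gene_a`, `gene_b`, `weight`); edges whose
#'   endpoints are not in the node set are dropped with a warning.
#' @param omics_tables A data frame or list of data frames, each with a
#'   `gene_id` column followed by numeric feature columns (`NA` = missing).
#' @param split_masks Named character vector over the labeled genes with
#'   values in `"train"`, `"val"`, `"test"` (see [stratified_holdout()] and
#'   [kfold_assign()]).
#' @return Object of class `gene_graph`: list with `node_ids`, `features`
#'   (z-scored matrix), `edges`, `labels` (1/0/NA per node), `mask`
#'   (train/val/test/none per node), and `preprocess` (fitted imputation and
#'   scaling parameters).
#' @export
assemble_graph <- function(candidates, labels, edges, omics_tables,
                           split_masks) {
  stopifnot(inherits(labels, "label_set"))
  if (is.data.frame(omics_tables)) omics_tables <- list(omics_tables)
  labeled <- c(labels$positives, labels$negatives)
  node_ids <- sort(unique(c(as.character(candidates), labeled)))
  n <- length(node_ids)
  if (n == 0L) stop("empty node set")

  y <- rep(NA_integer_, n); names(y) <- node_ids
  y[node_ids %in% labels$positives] <- 1L
  y[node_ids %in% labels$negatives] <- 0L

  mask <- rep("none", n); names(mask) <- node_ids
  if (!all(names(split_masks) %in% node_ids))
    stop("split_masks refers to genes outside the node set")
  if (!all(split_masks %in% c("train", "val", "test")))
    stop("split_masks values must be train/val/test")
  mask[names(split_masks)] <- split_masks
  if (any(mask[!is.na(y)] == "none"))
    stop("every labeled gene needs a train/val/test mask")

  blocks <- lapply(omics_tables, function(tab) {
    if (!"gene_id" %in% names(tab))
      stop("each omics table needs a gene_id column")
    m <- as.matrix(tab[, setdiff(names(tab), "gene_id"), drop = FALSE])
    storage.mode(m) <- "double"
    out <- matrix(NA_real_, n, ncol(m),
                  dimnames = list(node_ids, colnames(m)))
    hit <- match(node_ids, tab$gene_id)
    out[!is.na(hit), ] <- m[hit[!is.na(hit)], , drop = FALSE]
    out
  })
  features <- do.call(cbind, blocks)
  all_missing <- rowSums(!is.na(features)) == 0L
  if (any(all_missing))
    warning(sum(all_missing), " gene(s) missing from every omics table; ",
            "rows filled with training medians")

  features_raw <- features
  pp <- fit_preprocess(features, which(mask == "train"))
  features <- apply_preprocess(features, pp)

  keep <- edges$gene_a %in% node_ids & edges$gene_b %in% node_ids
  if (!all(keep))
    warning(sum(!keep), " edge(s) dropped: endpoint outside the node set")
  edges <- edges[keep, , drop = FALSE]
  edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
  rownames(edges) <- NULL

  structure(list(node_ids = node_ids, features = features,
                 features_raw = features_raw, edges = edges,
                 labels = y, mask = mask, preprocess = pp),
            class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  n_lab <- sum(!is.na(x$labels))
  cat("gene_graph: ", length(x$node_ids), " nodes, ", nrow(x$edges),
      " edges, ", ncol(x$features), " features\n",
      "  labeled: ", n_lab, " (", sum(x$labels == 1L, na.rm = TRUE),
      " positive / ", sum(x$labels == 0L, na.rm = TRUE), " negative)\n",
      "  masks: ", sum(x$mask == "train"), " train, ",
      sum(x$mask == "val"), " val, ", sum(x$mask == "test"), " test\n",
      sep = "")
  invisible(x)
}

# adjacency in directed edge-list form with self-loops, for the encoder
graph_adjacency <- function(graph, drop_edges = FALSE) {
  n <- length(graph$node_ids)
  if (drop_edges || nrow(graph$edges) == 0L) {
    src <- dst <- seq_len(n)
    w <- numeric(n)
  } else {
    ia <- match(graph$edges$gene_a, graph$node_ids)
    ib <- match(graph$edges$gene_b, graph$node_ids)
    src <- c(ia, ib, seq_len(n))
    dst <- c(ib, ia, seq_len(n))
    w <- c(graph$edges$weight, graph$edges$weight, numeric(n))
  }
  list(src = src, dst = dst, weight = w, n = n)
}
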