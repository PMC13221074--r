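## Plain-text readers and writers for the pipeline's input and output
## dialects.  GWAS summary statistics and interaction lists are headered
## TSV; gene coordinates are 4-column BED (0-based half-open, no header).

#' Read GWAS summary statistics
#'
#' Expects a headered TSV with columns `SNP`, `CHR`, `BP`, `P`.
#'
#' @param path File path.
#' @return Data frame with columns `snp_id`, `chrom`, `pos`, `p_value`.
#' @export
read_gwas_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("SNP", "CHR", "BP", "P")
  if (!all(need %in% names(d)))
    stop("GWAS file must have columns ", paste(need, collapse = ", "))
  validate_snps(data.frame(snp_id = as.character(d$SNP),
                           chrom = as.character(d$CHR),
                           pos = as.integer(d$BP), p_value = as.numeric(d$P),
                           stringsAsFactors = FALSE))
}

#' Read gene coordinates (BED)
#'
#' 4-column BED: chrom, start, end, gene_id; 0-based half-open, no header.
#'
#' @param path File path.
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_bed <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 4L) stop("BED file needs 4 columns: chrom start end name")
  validate_genes(data.frame(gene_id = as.character(d[[4L]]),
                            chrom = as.character(d[[1L]]),
                            start = as.integer(d[[2L]]),
                            end = as.integer(d[[3L]]),
                            stringsAsFactors = FALSE))
}

#' Read a SNP-SNP interaction list
#'
#' Headered TSV with columns `snp_a`, `snp_b`, `p` (or `p_interaction`).
#'
#' @param path File path.
#' @return Data frame with columns `snp_a`, `snp_b`, `p_interaction`.
#' @export
read_interactions_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("p" %in% names(d) && !"p_interaction" %in% names(d))
    names(d)[names(d) == "p"] <- "p_interaction"
  if (!all(c("snp_a", "snp_b", "p_interaction") %in% names(d)))
    stop("interaction file must have columns snp_a, snp_b, p")
  d[c("snp_a", "snp_b", "p_interaction")]
}

#' Read an omics feature table
#'
#' Headered TSV: `gene_id` followed by numeric feature columns; empty
#' cells are missing values.
#'
#' @param path File path.
#' @return Data frame with `gene_id` and numeric columns.
#' @export
read_omics_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  if (!"gene_id" %in% names(d)) stop("omics table needs a gene_id column")
  for (j in setdiff(names(d), "gene_id")) d[[j]] <- as.numeric(d[[j]])
  d
}

#' Read a gene label list
#'
#' Headered TSV with columns `gene_id` and `label` (1 = positive,
#' 0 = negative).
#'
#' @param path File path.
#' @return A [label_set()].
#' @export
read_labels_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "label") %in% names(d)))
    stop("label file must have columns gene_id, label")
  if (!all(d$label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  label_set(d$gene_id[d$label == 1L], d$gene_id[d$label == 0L])
}

#' Read an unordered gene-pair list
#'
#' Headered TSV whose first two columns name interacting genes.
#'
#' @param path File path.
#' @return Two-column data frame.
#' @export
read_pairs_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("pair list needs two columns")
  d[1:2]
}

#' Read an expression matrix with its sample-group map
#'
#' @param expr_path Headered TSV: `gene_id` plus one numeric column per
#'   sample.
#' @param groups_path Headered TSV with columns `sample`, `group`.
#' @return List with `values` (matrix) and `sample_group`.
#' @export
read_expression_tsv <- function(expr_path, groups_path) {
  d <- utils::read.delim(expr_path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(d)) stop("expression table needs gene_id")
  m <- as.matrix(d[setdiff(names(d), "gene_id")])
  rownames(m) <- d$gene_id
  g <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(g)))
    stop("group map needs columns sample, group")
  idx <- match(colnames(m), g$sample)
  if (anyNA(idx)) stop("sample missing from group map")
  list(values = m, sample_group = g$group[idx])
}

#' Write a gene-edge list
#'
#' TSV with columns `gene_a`, `gene_b`, `weight` (6 decimal places).
#'
#' @param edges Edge data frame.
#' @param path Output path.
#' @export
write_edges_tsv <- function(edges, path) {
  out <- edges
  out$weight <- sprintf("%.6f", out$weight)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write per-gene predictions
#'
#' TSV with columns `gene_id`, `probability`, `class`.
#'
#' @param predictions Data frame from [predict.protogt()].
#' @param path Output path.
#' @export
write_predictions_tsv <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
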