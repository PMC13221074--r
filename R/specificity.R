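## Post-hoc characterization of predicted gene sets: tissue specificity
## from the Jensen-Shannon divergence, cell-type specificity from group
## mean-expression proportions, rank-sum comparison of high-risk versus
## low-risk genes, and one-sided Fisher gene-set enrichment.
##
## Entropies are measured in bits (base 2) so the JS divergence of two
## distributions lies in [0, 1] and the specificity score 1 - sqrt(JS)
## stays in [0, 1].

#' Normalize an expression vector to a density
#'
#' Divides a gene's nonnegative per-tissue expression vector by its total.
#' All-zero genes cannot be normalized and return `NULL` (such genes are
#' excluded from specificity scoring rather than assigned a score).
#'
#' @param V Nonnegative numeric vector with at least 2 entries.
#' @return Probability vector summing to 1, or `NULL` for an all-zero
#'   input.
#' @export
density_normalize <- function(V) {
  if (length(V) < 2L) stop("need at least 2 tissues")
  if (any(V < 0) || any(!is.finite(V))) stop("expression must be >= 0")
  s <- sum(V)
  if (s == 0) return(NULL)
  V / s
}

entropy_bits <- function(p) {
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Jensen-Shannon divergence (bits)
#'
#' `JS(p1, p2) = H((p1 + p2)/2) - (H(p1) + H(p2))/2` with base-2 entropy
#' and the convention `0 * log 0 = 0`.  Symmetric, nonnegative, and
#' bounded by 1 bit (attained for disjoint supports).
#'
#' @param p1,p2 Probability vectors of equal length summing to 1.
#' @return Divergence in `[0, 1]`.
#' @export
js_divergence <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("length mismatch")
  if (any(p1 < 0) || any(p2 < 0)) stop("negative probability")
  if (abs(sum(p1) - 1) > 1e-6 || abs(sum(p2) - 1) > 1e-6)
    stop("inputs must sum to 1")
  entropy_bits((p1 + p2) / 2) - (entropy_bits(p1) + entropy_bits(p2)) / 2
}

#' Tissue specificity score
#'
#' `TS(E | t) = 1 - sqrt(JS(E, E_t))` where `E_t` is the indicator
#' distribution concentrated on tissue `t`: the square root of the JS
#' divergence is the distance between expression patterns, and the score
#' is 1 exactly when the gene is expressed only in tissue `t`.
#' `sqrt = FALSE` uses the raw divergence as the distance instead.
#'
#' @param E Density vector from [density_normalize()].
#' @param t Tissue index in `1..length(E)`.
#' @param sqrt Use the square-root (metric) form of the distance
#'   (default `TRUE`).
#' @return Score in `[0, 1]`.
#' @export
tissue_specificity <- function(E, t, sqrt = TRUE) {
  if (is.null(E)) return(NA_real_)
  stopifnot(t >= 1, t <= length(E))
  Et <- numeric(length(E)); Et[t] <- 1
  js <- js_divergence(E, Et)
  1 - if (sqrt) base::sqrt(js) else js
}

#' Per-gene tissue specificity matrix
#'
#' Averages expression within each tissue/group, density-normalizes each
#' gene's per-group profile, and scores every gene against every group with
#' [tissue_specificity()].  All-zero genes get `NA` rows.
#'
#' @param values Nonnegative matrix, genes x samples (rownames = gene ids).
#' @param sample_group Group label per sample (length `ncol(values)`);
#'   `NULL` when columns are already one per tissue.
#' @param sqrt Passed to [tissue_specificity()].
#' @return Matrix genes x groups of specificity scores.
#' @export
tissue_specificity_scores <- function(values, sample_group = NULL,
                                      sqrt = TRUE) {
  gm <- group_means(values, sample_group)
  out <- matrix(NA_real_, nrow(gm), ncol(gm), dimnames = dimnames(gm))
  for (g in seq_len(nrow(gm))) {
    E <- density_normalize(gm[g, ])
    if (is.null(E)) next
    for (t in seq_len(ncol(gm))) out[g, t] <- tissue_specificity(E, t, sqrt)
  }
  out
}

group_means <- function(values, sample_group = NULL) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("expression must be nonnegative")
  if (is.null(sample_group)) return(values)
  if (length(sample_group) != ncol(values))
    stop("one group label per sample required")
  groups <- unique(sample_group)
  if (length(groups) < 2L) stop("need at least 2 groups")
  gm <- matrix(0, nrow(values), length(groups),
               dimnames = list(rownames(values), groups))
  for (k in seq_along(groups))
    gm[, k] <- rowMeans(values[, sample_group == groups[k], drop = FALSE])
  gm
}

#' Cell-type specificity scores
#'
#' For each gene, the mean expression within each cell type divided by the
#' sum of the per-type means: `S_{g,c} = mean_c(g) / sum_j mean_j(g)`.
#' Scores sum to 1 across cell types for every scorable gene and are
#' invariant to rescaling a gene's expression by a positive constant.
#' Genes with zero mean in every type are flagged with `NA`.
#'
#' @param values Nonnegative matrix, genes x cells (rownames = gene ids).
#' @param sample_group Cell-type label per column.
#' @return Matrix genes x cell types of specificity scores.
#' @export
cell_type_specificity <- function(values, sample_group) {
  gm <- group_means(values, sample_group)
  tot <- rowSums(gm)
  out <- gm / tot
  out[tot == 0, ] <- NA_real_
  out
}

#' Compare specificity between high- and low-risk genes
#'
#' One-sided Wilcoxon rank-sum test per group of the hypothesis that the
#' high-risk genes' specificity scores are stochastically greater than the
#' low-risk genes', with Benjamini-Hochberg adjustment across the groups
#' tested.  The exact p-value is used for small tie-free samples (the
#' normal approximation with tie correction otherwise).  Groups with fewer
#' than 3 scorable genes on either side are skipped with a warning.
#'
#' @param hrg_scores,lrg_scores Score matrices (genes x groups) with
#'   matching columns, e.g. from [tissue_specificity_scores()] or
#'   [cell_type_specificity()].
#' @param alternative Test direction (default `"greater"`: HRG scores
#'   larger).
#' @return Data frame with columns `group`, `statistic`, `p_value`,
#'   `p_adjusted`, `significant` (adjusted p < 0.05).
#' @export
compare_specificity <- function(hrg_scores, lrg_scores,
                                alternative = "greater") {
  if (is.null(dim(hrg_scores))) hrg_scores <- cbind(group = hrg_scores)
  if (is.null(dim(lrg_scores))) lrg_scores <- cbind(group = lrg_scores)
  if (ncol(hrg_scores) != ncol(lrg_scores))
    stop("score matrices must have the same groups")
  groups <- colnames(hrg_scores)
  if (is.null(groups)) groups <- as.character(seq_len(ncol(hrg_scores)))
  stat <- p <- rep(NA_real_, length(groups))
  for (k in seq_along(groups)) {
    a <- hrg_scores[, k]; a <- a[!is.na(a)]
    b <- lrg_scores[, k]; b <- b[!is.na(b)]
    if (length(a) < 3L || length(b) < 3L) {
      warning("group ", groups[k], " skipped: fewer than 3 observations ",
              "per side")
      next
    }
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = alternative))
    stat[k] <- unname(wt$statistic)
    p[k] <- wt$p.value
  }
  padj <- rep(NA_real_, length(groups))
  padj[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  data.frame(group = groups, statistic = stat, p_value = p,
             p_adjusted = padj,
             significant = !is.na(padj) & padj < 0.05,
             stringsAsFactors = FALSE)
}

#' One-sided Fisher gene-set enrichment
#'
#' Tests each annotation gene set for over-representation in the query set
#' against the background universe with the one-sided Fisher exact
#' (hypergeometric) test, adjusting across the gene-set family by
#' Benjamini-Hochberg.  Annotations are intersected with the background
#' before tabulation.
#'
#' @param query Character vector of genes (must be a subset of
#'   `background`).
#' @param annotations Named list of gene sets (a single character vector is
#'   treated as a one-set family).
#' @param background Character vector: the gene universe.
#' @return Data frame with columns `set`, `n_query`, `n_set`, `overlap`,
#'   `odds_ratio`, `p_value`, `p_adjusted`, `significant` (adjusted
#'   p < 0.05).
#' @export
fisher_enrichment <- function(query, annotations, background) {
  if (!length(background)) stop("empty background")
  background <- unique(background)
  query <- unique(query)
  if (!all(query %in% background))
    stop("`query` must be a subset of `background`")
  if (!is.list(annotations)) annotations <- list(set1 = annotations)
  if (is.null(names(annotations)))
    names(annotations) <- paste0("set", seq_along(annotations))
  res <- lapply(names(annotations), function(nm) {
    ann <- intersect(unique(annotations[[nm]]), background)
    a <- length(intersect(query, ann))
    b <- length(setdiff(query, ann))
    cc <- length(setdiff(ann, query))
    d <- length(background) - a - b - cc
    ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2L, byrow = TRUE),
                             alternative = "greater")
    data.frame(set = nm, n_query = length(query), n_set = length(ann),
               overlap = a, odds_ratio = unname(ft$estimate),
               p_value = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adjusted < 0.05
  rownames(out) <- NULL
  out
}
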