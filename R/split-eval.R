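## Data splitting, neighbor-sampled batch construction, operating-point
## selection, and ranking metrics.

#' Stratified train/test holdout split
#'
#' Splits labeled genes into a training and a hold-out test set while
#' preserving per-class proportions to within rounding.  Deterministic for
#' a given seed.
#'
#' @param labels Named binary vector (names = gene ids, values 0/1).
#' @param fraction Fraction of each class assigned to the training set
#'   (default 0.8).
#' @param seed Integer seed.
#' @return List with character vectors `train` and `test`.
#' @export
stratified_holdout <- function(labels, fraction = 0.8, seed = 0L) {
  stopifnot(fraction > 0, fraction < 1, !is.null(names(labels)))
  labels <- labels[!is.na(labels)]
  train <- character(0)
  for (cl in c(0L, 1L)) {
    ids <- names(labels)[labels == cl]
    if (length(ids) < 2L)
      stop("class ", cl, " has fewer than 2 members")
    n_tr <- round(fraction * length(ids))
    n_tr <- min(max(n_tr, 1L), length(ids) - 1L)
    set.seed(seed + cl)
    train <- c(train, sample(ids, n_tr))
  }
  list(train = sort(train), test = sort(setdiff(names(labels), train)))
}

#' Stratified k-fold assignment
#'
#' Assigns each training gene to one of `k` folds, stratified by class so
#' fold class counts differ by at most one from the exact stratified count.
#'
#' @param ids Character vector of training gene ids.
#' @param labels Named binary vector covering `ids`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Named integer vector of fold indices in `1..k`.
#' @export
kfold_assign <- function(ids, labels, k = 5L, seed = 0L) {
  k <- as.integer(k)
  stopifnot(k >= 2L)
  fold <- integer(length(ids))
  names(fold) <- ids
  for (cl in unique(labels[ids])) {
    cl_ids <- ids[labels[ids] == cl]
    if (length(cl_ids) < k)
      warning("class ", cl, " has fewer members than folds; ",
              "some folds lack this class")
    set.seed(seed + as.integer(cl))
    perm <- sample(cl_ids)
    fold[perm] <- rep_len(seq_len(k), length(perm))
  }
  fold
}

# adjacency list (undirected neighbors) from a gene_graph
neighbor_list <- function(graph) {
  n <- length(graph$node_ids)
  nb <- vector("list", n)
  if (nrow(graph$edges)) {
    ia <- match(graph$edges$gene_a, graph$node_ids)
    ib <- match(graph$edges$gene_b, graph$node_ids)
    for (k in seq_along(ia)) {
      nb[[ia[k]]] <- c(nb[[ia[k]]], ib[k])
      nb[[ib[k]]] <- c(nb[[ib[k]]], ia[k])
    }
    nb <- lapply(nb, unique)
  }
  nb
}

#' Extract the two-hop subgraph around a set of center nodes
#'
#' Returns the induced subgraph on the centers together with all their
#' first- and second-order neighbors, preserving edge weights and tagging
#' the center nodes.
#'
#' @param graph A `gene_graph`.
#' @param centers Character vector of center gene ids (or integer indices).
#' @return List with `node_ids`, `edges` (induced, original weights),
#'   `centers` (ids), and `hop` (0 = center, 1, 2) per node.
#' @export
sample_subgraph <- function(graph, centers) {
  if (is.character(centers)) {
    cidx <- match(centers, graph$node_ids)
    if (anyNA(cidx)) stop("unknown center gene id")
  } else cidx <- as.integer(centers)
  nb <- neighbor_list(graph)
  h1 <- unique(unlist(nb[cidx]))
  h2 <- unique(unlist(nb[h1]))
  hop <- rep(2L, length(graph$node_ids))
  hop[h2] <- 2L
  hop[h1] <- 1L
  hop[cidx] <- 0L
  keep <- sort(unique(c(cidx, h1, h2)))
  ids <- graph$node_ids[keep]
  e <- graph$edges
  sel <- e$gene_a %in% ids & e$gene_b %in% ids
  list(node_ids = ids, edges = e[sel, , drop = FALSE],
       centers = graph$node_ids[cidx], hop = hop[keep])
}

# internal batch for the encoder: local edge list with self-loops plus
# per-center pooling sets ("neighborhood" = closed 1-hop, "subgraph" =
# closed 2-hop, computed within the batch)
make_batch <- function(graph, nb, cidx, pool) {
  h1 <- lapply(cidx, function(i) nb[[i]])
  h1all <- unique(unlist(h1))
  h2all <- unique(unlist(nb[h1all]))
  nodes <- sort(unique(c(cidx, h1all, h2all)))
  local <- integer(length(graph$node_ids))
  local[nodes] <- seq_along(nodes)
  n <- length(nodes)
  if (nrow(graph$edges)) {
    ia <- match(graph$edges$gene_a, graph$node_ids)
    ib <- match(graph$edges$gene_b, graph$node_ids)
    sel <- local[ia] > 0L & local[ib] > 0L
    la <- local[ia[sel]]; lb <- local[ib[sel]]
    w <- graph$edges$weight[sel]
    src <- c(la, lb, seq_len(n))
    dst <- c(lb, la, seq_len(n))
    w <- c(w, w, numeric(n))
  } else {
    src <- dst <- seq_len(n); w <- numeric(n)
  }
  pool_sets <- vector("list", length(cidx))
  for (ci in seq_along(cidx)) {
    if (pool == "neighborhood") {
      set <- c(cidx[ci], h1[[ci]])
    } else {
      set <- unique(c(cidx[ci], h1[[ci]], unlist(nb[h1[[ci]]])))
    }
    pool_sets[[ci]] <- local[set]
  }
  list(nodes = nodes, src = src, dst = dst, weight = w, n = n,
       dst_groups = make_groups(dst, n), pool_sets = pool_sets)
}

#' Youden-index threshold selection
#'
#' Scans the unique observed scores as candidate thresholds under the rule
#' `predict positive iff score >= threshold` and returns the threshold
#' maximizing Youden's J = sensitivity + specificity - 1.  Ties are broken
#' by higher sensitivity, then by the lower threshold.
#'
#' @param scores Numeric probabilities/scores.
#' @param labels Binary labels (both classes must be present).
#' @return The selected threshold, with the achieved index value in
#'   attribute `"youden"`.
#' @export
youden_threshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to choose a threshold")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  cand <- sort(unique(scores))
  best <- NULL
  for (t in cand) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1L) / n_pos
    spec <- sum(!pred & labels == 0L) / n_neg
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 &&
         (sens > best$sens + 1e-12 ||
          (abs(sens - best$sens) <= 1e-12 && t < best$t)))) {
      best <- list(t = t, j = j, sens = sens)
    }
  }
  structure(best$t, youden = best$j)
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) AUROC with ties averaged.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes required")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average precision: the sum over positives, in decreasing-score order, of
#' precision at each positive's rank (step-wise, no interpolation).
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop("no positive labels")
  ord <- order(-scores)
  y <- labels[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  sum(prec[y == 1L]) / n_pos
}

#' Evaluate scores against labels
#'
#' Computes AUROC (rank statistic, ties averaged), AUPRC (average
#' precision), and the F1-score of the positive class at the supplied
#' threshold (`score >= threshold` predicts positive).
#'
#' @inheritParams auroc
#' @param threshold Decision threshold.
#' @param ids Optional gene ids for the per-gene table.
#' @return Object of class `pgt_eval`: list with `auroc`, `auprc`, `f1`,
#'   `threshold`, `n_pos`, `n_neg`, and `per_gene` (gene_id, probability,
#'   class HRG/LRG).
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5, ids = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes required")
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  structure(list(auroc = auroc(scores, labels),
                 auprc = auprc(scores, labels),
                 f1 = f1, threshold = as.numeric(threshold),
                 n_pos = sum(labels == 1L), n_neg = sum(labels == 0L),
                 per_gene = data.frame(gene_id = ids, probability = scores,
                                       class = ifelse(pred, "HRG", "LRG"),
                                       stringsAsFactors = FALSE)),
            class = "pgt_eval")
}

#' @export
print.pgt_eval <- function(x, ...) {
  cat(sprintf(
    "evaluation (%d pos / %d neg): AUROC %.4f, AUPRC %.4f, F1 %.4f @ threshold %.4f\n",
    x$n_pos, x$n_neg, x$auroc, x$auprc, x$f1, x$threshold))
  invisible(x)
}

#' Random-classifier AUPRC baseline
#'
#' The expected AUPRC of an uninformative classifier equals the positive
#' prevalence `n_pos / (n_pos + n_neg)`.
#'
#' @param n_pos,n_neg Class counts.
#' @return The prevalence baseline.
#' @export
random_baseline_auprc <- function(n_pos, n_neg) {
  stopifnot(n_neg >= 0)
  if (n_pos < 1) stop("`n_pos` must be at least 1")
  n_pos / (n_pos + n_neg)
}

#' Partition scored genes into high- and low-risk sets
#'
#' @param probabilities Named numeric vector of per-gene probabilities.
#' @param threshold Decision threshold (probability `>=` threshold is
#'   high-risk).
#' @return List with character vectors `hrg` and `lrg`.
#' @export
classify_genes <- function(probabilities, threshold) {
  if (is.null(names(probabilities)))
    names(probabilities) <- as.character(seq_along(probabilities))
  hi <- probabilities >= threshold
  list(hrg = names(probabilities)[hi], lrg = names(probabilities)[!hi])
}
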