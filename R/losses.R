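## The three loss components: prototype similarity / contrastive loss,
## focal classification loss, and their unweighted sum.  Exported functions
## compute values; the internal *_grad helpers return the analytic
## gradients consumed by the trainer (verified against finite differences
## in the test suite).

#' Prototype similarity score
#'
#' Similarity between an embedding and a prototype vector,
#' `g = log((D + 1) / (D + epsilon))` with `D` the squared Euclidean
#' distance.  The score is `log(1/epsilon)` at distance 0, strictly
#' decreasing in `D`, and tends to 0 as `D` grows.
#'
#' @param v_n Numeric embedding vector.
#' @param v_p Numeric prototype vector of the same length.
#' @param epsilon Stabilizer in (0, 1].
#' @return Scalar similarity.
#' @export
prototype_similarity <- function(v_n, v_p, epsilon = 1e-4) {
  if (length(v_n) != length(v_p)) stop("vectors differ in length")
  if (!all(is.finite(v_n)) || !all(is.finite(v_p)))
    stop("non-finite input")
  stopifnot(epsilon > 0)
  D <- sum((v_n - v_p)^2)
  log((D + 1) / (D + epsilon))
}

# similarity matrix between rows of E (N x d) and rows of P (K x d),
# plus squared distances (needed by the backward pass)
proto_similarity_matrix <- function(E, P, epsilon) {
  D2 <- outer(rowSums(E^2), rowSums(P^2), `+`) - 2 * E %*% t(P)
  D2 <- pmax(D2, 0)
  list(g = log((D2 + 1) / (D2 + epsilon)), D2 = D2)
}

#' Prototype-contrastive loss
#'
#' For each node `i` with class `y_i`, similarities `g` to every prototype
#' are converted to a contrast of the node's own-class prototypes against
#' the prototypes of the other classes:
#' `L = -(1/N) * sum_i log( sum_{m in class y_i} exp(g_im / T) /
#' sum_{j not in class y_i} exp(g_ij / T) )`.
#' The denominator runs over the non-class prototypes only (the printed
#' form), so the loss may be negative; `denominator = "all"` switches to
#' the InfoNCE convention of summing over every prototype.
#'
#' @param embeddings Numeric matrix, one row per node.
#' @param labels Integer class per node (0-based or any labels matching
#'   `class_of`).
#' @param prototypes Numeric matrix, one row per prototype.
#' @param class_of Class of each prototype row (same coding as `labels`).
#' @param temperature Positive temperature `T`.
#' @param epsilon Similarity stabilizer.
#' @param denominator `"other"` (default) or `"all"`.
#' @return Scalar loss.
#' @export
prototype_contrastive_loss <- function(embeddings, labels, prototypes,
                                       class_of, temperature = 0.5,
                                       epsilon = 1e-4,
                                       denominator = c("other", "all")) {
  denominator <- match.arg(denominator)
  embeddings <- rbind(embeddings)
  prototypes <- rbind(prototypes)
  N <- nrow(embeddings)
  if (N == 0L) stop("empty batch")
  if (length(labels) != N) stop("labels must match embeddings rows")
  if (length(class_of) != nrow(prototypes))
    stop("class_of must match prototype rows")
  for (cl in unique(labels)) {
    if (!any(class_of == cl)) stop("class ", cl, " has no prototypes")
    if (!any(class_of != cl)) stop("class ", cl, " has no negative prototypes")
  }
  stopifnot(temperature > 0)
  g <- proto_similarity_matrix(embeddings, prototypes, epsilon)$g
  loss_from_similarities(g, labels, class_of, temperature, denominator)$loss
}

# log-sum-exp by row over a logical column mask
row_lse <- function(M, mask) {
  sub <- M[, mask, drop = FALSE]
  mx <- apply(sub, 1L, max)
  mx + log(rowSums(exp(sub - mx)))
}

loss_from_similarities <- function(g, labels, class_of, temperature,
                                   denominator) {
  N <- nrow(g)
  s <- g / temperature
  pos_lse <- neg_lse <- numeric(N)
  W <- matrix(0, N, ncol(g))   # d(loss)/d(g) * N  (per-node softmax weights)
  for (cl in unique(labels)) {
    rows <- which(labels == cl)
    pos <- class_of == cl
    neg <- if (denominator == "other") !pos else rep(TRUE, length(class_of))
    pos_lse[rows] <- row_lse(s[rows, , drop = FALSE], pos)
    neg_lse[rows] <- row_lse(s[rows, , drop = FALSE], neg)
    sp <- exp(s[rows, pos, drop = FALSE] - pos_lse[rows])
    sn <- exp(s[rows, neg, drop = FALSE] - neg_lse[rows])
    W[rows, pos] <- W[rows, pos, drop = FALSE] - sp
    W[rows, neg] <- W[rows, neg, drop = FALSE] + sn
  }
  list(loss = mean(neg_lse - pos_lse),
       dg = W / (N * temperature))
}

# loss value and gradients wrt embeddings E and prototypes P
proto_loss_grad <- function(E, P, labels, class_of, temperature, epsilon,
                            denominator = "other") {
  sim <- proto_similarity_matrix(E, P, epsilon)
  lf <- loss_from_similarities(sim$g, labels, class_of, temperature,
                               denominator)
  # dg/dD2 = 1/(D2+1) - 1/(D2+eps); dD2/dE_i = 2(E_i - P_k)
  dD2 <- lf$dg * (1 / (sim$D2 + 1) - 1 / (sim$D2 + epsilon))
  dE <- 2 * (rowSums(dD2) * E - dD2 %*% P)
  dP <- 2 * (colSums(dD2) * P - t(dD2) %*% E)
  list(loss = lf$loss, dE = dE, dP = dP)
}

#' Focal loss
#'
#' Class-weighted focal cross-entropy
#' `FL = -alpha_t * (1 - p_t)^gamma * log(p_t)` with `p_t = p` for `y = 1`
#' and `1 - p` for `y = 0`, and `alpha_t = alpha` / `1 - alpha`
#' correspondingly.  Probabilities are clipped to `[1e-7, 1 - 1e-7]`.
#' Vectorized; returns the mean over the supplied nodes.
#'
#' @param p Predicted probability (or vector) of the positive class.
#' @param y Ground-truth class in \{0, 1\} (recycled against `p`).
#' @param alpha Weighting factor in `[0, 1]` (default 0.25).
#' @param gamma Focusing parameter `>= 0` (default 2).
#' @return Mean focal loss (nonnegative scalar).
#' @export
focal_loss <- function(p, y, alpha = 0.25, gamma = 2) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  pt <- ifelse(y == 1, p, 1 - p)
  at <- ifelse(y == 1, alpha, 1 - alpha)
  mean(-at * (1 - pt)^gamma * log(pt))
}

# d(mean focal)/d(logit z), with p = sigmoid(z); vectorized
focal_grad_logit <- function(p, y, alpha, gamma) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  pt <- ifelse(y == 1, p, 1 - p)
  at <- ifelse(y == 1, alpha, 1 - alpha)
  # dFL/dpt = at * (gamma*(1-pt)^(gamma-1)*log(pt) - (1-pt)^gamma/pt)
  dpt <- at * (gamma * (1 - pt)^pmax(gamma - 1, 0) * log(pt) -
                 (1 - pt)^gamma / pt)
  dp <- ifelse(y == 1, dpt, -dpt)
  dp * p * (1 - p) / length(p)
}

#' Total training objective
#'
#' The unweighted sum of the focal classification loss and the
#' prototype-contrastive loss.
#'
#' @param focal Focal-loss value.
#' @param l_pl Prototype-contrastive loss value.
#' @return `focal + l_pl`.
#' @export
total_loss <- function(focal, l_pl) {
  stopifnot(is.finite(focal), is.finite(l_pl))
  focal + l_pl
}
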