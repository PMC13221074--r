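## Internal neural-network core: parameter initialization, the edge-
## restricted multi-head attention encoder with layer normalization,
## max-pool readout and fully connected head, the analytic backward pass,
## and an Adam optimizer.  All gradients are hand-derived and checked
## against central finite differences in the test suite.
##
## Batches are edge lists (src -> dst) with self-loops; a node attends over
## its in-neighbors (and itself), and the edge weight enters as an additive
## bias on the pre-softmax attention score (self-loops have bias 0).

LN_EPS <- 1e-5

init_params <- function(d_in, cfg, seed) {
  set.seed(seed)
  gl <- function(nr, nc) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
  }
  h <- cfg$hidden_dim
  layers <- vector("list", cfg$n_layers)
  din <- d_in
  for (l in seq_len(cfg$n_layers)) {
    layers[[l]] <- list(Wq = gl(din, h), Wk = gl(din, h), Wv = gl(din, h),
                        Wo = gl(h, h), bo = numeric(h),
                        ln_g = rep(1, h), ln_b = numeric(h))
    din <- h
  }
  K <- cfg$n_classes * cfg$prototypes_per_class
  list(layers = layers,
       W1 = gl(h, h), b1 = numeric(h),
       W2 = gl(h, 1L), b2 = 0,
       proto = matrix(stats::rnorm(K * h) / sqrt(h), K, h),
       proto_class = rep(seq_len(cfg$n_classes) - 1L,
                         each = cfg$prototypes_per_class))
}

# per-destination index groups for the softmax; computed once per batch
make_groups <- function(idx, n) {
  split(seq_along(idx), factor(idx, levels = seq_len(n)))
}

group_max <- function(x, groups) {
  vapply(groups, function(ii) max(x[ii]), 0)
}

# multi-head attention layer forward; returns output and a cache for
# the backward pass
attn_forward <- function(X, lay, batch, n_heads) {
  h <- ncol(lay$Wq)
  dh <- h %/% n_heads
  Q <- X %*% lay$Wq
  K <- X %*% lay$Wk
  V <- X %*% lay$Wv
  src <- batch$src; dst <- batch$dst
  QK <- Q[dst, , drop = FALSE] * K[src, , drop = FALSE]
  alpha <- matrix(0, length(src), n_heads)
  A <- matrix(0, batch$n, h)
  for (hd in seq_len(n_heads)) {
    cols <- ((hd - 1L) * dh + 1L):(hd * dh)
    s <- rowSums(QK[, cols, drop = FALSE]) / sqrt(dh) + batch$weight
    m <- group_max(s, batch$dst_groups)
    es <- exp(s - m[dst])
    denom <- rowsum(es, dst)[, 1L]
    alpha[, hd] <- es / denom[dst]
    A[, cols] <- rowsum(alpha[, hd] * V[src, cols, drop = FALSE], dst)
  }
  H <- A %*% lay$Wo
  H <- sweep(H, 2L, lay$bo, `+`)
  list(out = H, X = X, Q = Q, K = K, V = V, A = A, alpha = alpha, dh = dh)
}

attn_backward <- function(dH, lay, batch, cache, n_heads) {
  src <- batch$src; dst <- batch$dst
  dWo <- t(cache$A) %*% dH
  dbo <- colSums(dH)
  dA <- dH %*% t(lay$Wo)
  dh <- cache$dh
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- dQ; dV <- dQ
  for (hd in seq_len(n_heads)) {
    cols <- ((hd - 1L) * dh + 1L):(hd * dh)
    al <- cache$alpha[, hd]
    dAd <- dA[dst, cols, drop = FALSE]
    Vs <- cache$V[src, cols, drop = FALSE]
    dal <- rowSums(dAd * Vs)
    dV[, cols] <- dV[, cols, drop = FALSE] + rowsum(al * dAd, src)
    tsum <- rowsum(al * dal, dst)[, 1L]
    ds <- al * (dal - tsum[dst])
    dQ[, cols] <- dQ[, cols, drop = FALSE] +
      rowsum(ds * cache$K[src, cols, drop = FALSE], dst) / sqrt(dh)
    dK[, cols] <- dK[, cols, drop = FALSE] +
      rowsum(ds * cache$Q[dst, cols, drop = FALSE], src) / sqrt(dh)
  }
  X <- cache$X
  list(dWq = t(X) %*% dQ, dWk = t(X) %*% dK, dWv = t(X) %*% dV,
       dWo = dWo, dbo = dbo,
       dX = dQ %*% t(lay$Wq) + dK %*% t(lay$Wk) + dV %*% t(lay$Wv))
}

ln_forward <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  out <- sweep(xhat * rep(g, each = nrow(X)), 2L, b, `+`)
  # rep(g, each=nrow) broadcasts g across columns row-wise
  list(out = out, xc = xc, inv = inv, xhat = xhat)
}

ln_backward <- function(dY, g, cache) {
  n <- nrow(dY); d <- ncol(dY)
  dxhat <- dY * rep(g, each = n)
  dg <- colSums(dY * cache$xhat)
  db <- colSums(dY)
  inv <- cache$inv
  dvar <- rowSums(dxhat * cache$xc) * (-0.5) * inv^3
  dmu <- rowSums(dxhat) * (-inv)
  dX <- dxhat * inv + (2 / d) * dvar * cache$xc + dmu / d
  list(dX = dX, dg = dg, db = db)
}

# full forward pass over one batch; pool_sets is a list of local node-index
# vectors, one per center.  dropout_mask (C x h) is NULL in evaluation.
net_forward <- function(X, params, cfg, batch, pool_sets, dropout_mask) {
  caches <- vector("list", cfg$n_layers)
  Z <- X
  for (l in seq_len(cfg$n_layers)) {
    ac <- attn_forward(Z, params$layers[[l]], batch, cfg$n_heads)
    lc <- ln_forward(ac$out, params$layers[[l]]$ln_g, params$layers[[l]]$ln_b)
    caches[[l]] <- list(attn = ac, ln = lc)
    Z <- lc$out
  }
  h <- cfg$hidden_dim
  C <- length(pool_sets)
  pooled <- matrix(0, C, h)
  argmax <- matrix(0L, C, h)
  for (ci in seq_len(C)) {
    set <- pool_sets[[ci]]
    if (length(set) == 1L) {
      pooled[ci, ] <- Z[set, ]
      argmax[ci, ] <- set
    } else {
      sub <- Z[set, , drop = FALSE]
      am <- max.col(t(sub), ties.method = "first")
      argmax[ci, ] <- set[am]
      pooled[ci, ] <- sub[cbind(am, seq_len(h))]
    }
  }
  Hp <- if (is.null(dropout_mask)) pooled else pooled * dropout_mask
  A1 <- sweep(Hp %*% params$W1, 2L, params$b1, `+`)
  R1 <- pmax(A1, 0)
  z <- as.vector(R1 %*% params$W2) + params$b2
  p <- 1 / (1 + exp(-z))
  list(Z = Z, pooled = pooled, Hp = Hp, A1 = A1, R1 = R1,
       logits = z, prob = p, caches = caches, argmax = argmax,
       dropout_mask = dropout_mask)
}

# backward from d(loss)/d(logit) and d(loss)/d(Hp) (prototype term)
net_backward <- function(dz, dHp_extra, fwd, params, cfg, batch) {
  dW2 <- t(fwd$R1) %*% dz
  db2 <- sum(dz)
  dR1 <- dz %*% t(params$W2)
  dA1 <- dR1 * (fwd$A1 > 0)
  dW1 <- t(fwd$Hp) %*% dA1
  db1 <- colSums(dA1)
  dHp <- dA1 %*% t(params$W1)
  if (!is.null(dHp_extra)) dHp <- dHp + dHp_extra
  dpooled <- if (is.null(fwd$dropout_mask)) dHp else dHp * fwd$dropout_mask
  h <- cfg$hidden_dim
  dZ <- matrix(0, batch$n, h)
  cidx <- rep(seq_len(nrow(dpooled)), h)
  ridx <- as.vector(fwd$argmax)
  kidx <- rep(seq_len(h), each = nrow(dpooled))
  vals <- as.vector(dpooled)
  # accumulate into (argmax node, dimension); duplicates possible
  lin <- (kidx - 1L) * batch$n + ridx
  acc <- rowsum(vals, lin)
  dZ[as.integer(rownames(acc))] <- dZ[as.integer(rownames(acc))] + acc[, 1L]

  grads <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                layers = vector("list", cfg$n_layers))
  for (l in rev(seq_len(cfg$n_layers))) {
    cache <- fwd$caches[[l]]
    lay <- params$layers[[l]]
    lb <- ln_backward(dZ, lay$ln_g, cache$ln)
    ab <- attn_backward(lb$dX, lay, batch, cache$attn, cfg$n_heads)
    grads$layers[[l]] <- list(Wq = ab$dWq, Wk = ab$dWk, Wv = ab$dWv,
                              Wo = ab$dWo, bo = ab$dbo,
                              ln_g = lb$dg, ln_b = lb$db)
    dZ <- ab$dX
  }
  grads
}

## ---- flat parameter utilities (Adam, checkpoint comparison) ----

flatten_params <- function(p) {
  out <- list()
  for (l in seq_along(p$layers))
    for (nm in names(p$layers[[l]]))
      out[[paste0("L", l, ".", nm)]] <- p$layers[[l]][[nm]]
  out$W1 <- p$W1; out$b1 <- p$b1; out$W2 <- p$W2; out$b2 <- p$b2
  out$proto <- p$proto
  out
}

unflatten_params <- function(flat, skeleton) {
  for (l in seq_along(skeleton$layers))
    for (nm in names(skeleton$layers[[l]]))
      skeleton$layers[[l]][[nm]] <- flat[[paste0("L", l, ".", nm)]]
  skeleton$W1 <- flat$W1; skeleton$b1 <- flat$b1
  skeleton$W2 <- flat$W2; skeleton$b2 <- flat$b2
  skeleton$proto <- flat$proto
  skeleton
}

flatten_grads <- function(g, dproto) {
  out <- list()
  for (l in seq_along(g$layers))
    for (nm in names(g$layers[[l]]))
      out[[paste0("L", l, ".", nm)]] <- g$layers[[l]][[nm]]
  out$W1 <- g$W1; out$b1 <- g$b1; out$W2 <- g$W2; out$b2 <- g$b2
  out$proto <- dproto
  out
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

# names of parameters subject to weight decay (weight matrices only)
DECAY_RE <- "\\.(Wq|Wk|Wv|Wo)$|^W[12]$"

adam_step <- function(flat, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    if (weight_decay > 0 && grepl(DECAY_RE, nm))
      g <- g + weight_decay * flat[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    flat[[nm]] <- flat[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}
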