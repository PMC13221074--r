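#' Fit a prototype-augmented graph-transformer gene classifier
#'
#' Trains the semi-supervised node classifier on a labeled [gene_graph]:
#' mini-batches of train-mask center nodes are expanded to their two-hop
#' subgraphs (validation and test nodes may appear as unlabeled context but
#' never contribute labels or gradients), encoded by edge-restricted
#' multi-head attention layers with layer normalization, pooled by an
#' element-wise max readout, and classified through a two-layer head.  The
#' objective is the unweighted sum of a focal classification loss over the
#' supervised center nodes and a prototype-contrastive loss tying pooled
#' representations to learnable class prototypes.  Validation performance is
#' monitored every epoch; training stops early once it has not improved for
#' `patience` consecutive epochs and the best-validation checkpoint is
#' returned.  The decision threshold is chosen on the validation scores by
#' Youden's index.  The run is fully determined by the configs and seed.
#'
#' @param graph A [gene_graph] with `train` and `val` masks set (see
#'   [set_mask()]).
#' @param model A [pgt_model_config()] or list of overrides.
#' @param loss A [pgt_loss_config()] or list of overrides.
#' @param train A [pgt_train_config()] or list of overrides.
#' @param metric Validation metric for early stopping and model selection:
#'   `"auprc"` (default) or `"auroc"`.
#' @param no_edges Ablation: drop every edge and train on isolated nodes.
#' @param verbose Print per-epoch progress.
#' @return An object of class `protogt`: the fitted parameters, configs,
#'   training history (`epoch`, `train_loss`, `val_auprc`, `val_auroc`),
#'   best epoch, validation metrics, Youden threshold, and the training
#'   graph.
#' @seealso [predict.protogt()], [protogt_cv()]
#' @export
protogt <- function(graph, model = NULL, loss = NULL, train = NULL,
                    metric = c("auprc", "auroc"), no_edges = FALSE,
                    verbose = FALSE) {
  stopifnot(inherits(graph, "gene_graph"))
  metric <- match.arg(metric)
  model_cfg <- resolve_config(model, pgt_model_config)
  loss_cfg <- resolve_config(loss, pgt_loss_config)
  train_cfg <- resolve_config(train, pgt_train_config)
  if (no_edges) graph$edges <- graph$edges[0L, , drop = FALSE]

  y <- graph$labels
  train_idx <- which(graph$mask == "train" & !is.na(y))
  val_idx <- which(graph$mask == "val" & !is.na(y))
  if (length(train_idx) == 0L) stop("no labeled train-mask nodes")
  if (length(val_idx) == 0L) stop("no labeled val-mask nodes")
  if (length(unique(y[train_idx])) < 2L || length(unique(y[val_idx])) < 2L)
    stop("train and validation sets must each contain both classes")

  X <- graph$features
  if (anyNA(X)) stop("feature matrix contains missing values")
  nb <- neighbor_list(graph)
  params <- init_params(ncol(X), model_cfg, train_cfg$seed)
  flat <- flatten_params(params)
  state <- adam_init(flat)

  val_batch <- make_batch(graph, nb, val_idx, model_cfg$pool)
  val_X <- X[val_batch$nodes, , drop = FALSE]
  val_y <- y[val_idx]

  h <- model_cfg$hidden_dim
  best <- list(metric = -Inf, flat = flat, epoch = 0L)
  stall <- 0L
  history <- vector("list", train_cfg$max_epochs)

  for (epoch in seq_len(train_cfg$max_epochs)) {
    perm <- sample(train_idx)
    starts <- seq(1L, length(perm), by = train_cfg$batch_size)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      cidx <- perm[starts[bi]:min(starts[bi] + train_cfg$batch_size - 1L,
                                  length(perm))]
      batch <- make_batch(graph, nb, cidx, model_cfg$pool)
      Xb <- X[batch$nodes, , drop = FALSE]
      C <- length(cidx)
      dm <- if (model_cfg$dropout > 0) {
        matrix(stats::rbinom(C * h, 1L, 1 - model_cfg$dropout), C, h) /
          (1 - model_cfg$dropout)
      } else NULL
      fwd <- net_forward(Xb, params, model_cfg, batch, batch$pool_sets, dm)
      yb <- y[cidx]
      fl <- focal_loss(fwd$prob, yb, loss_cfg$focal_alpha,
                       loss_cfg$focal_gamma)
      dz <- focal_grad_logit(fwd$prob, yb, loss_cfg$focal_alpha,
                             loss_cfg$focal_gamma)
      if (loss_cfg$prototype_loss) {
        pg <- proto_loss_grad(fwd$Hp, params$proto, yb, params$proto_class,
                              loss_cfg$temperature, loss_cfg$epsilon,
                              loss_cfg$denominator)
        lpl <- pg$loss; dHp_extra <- pg$dE; dproto <- pg$dP
      } else {
        lpl <- 0; dHp_extra <- NULL; dproto <- params$proto * 0
      }
      losses[bi] <- total_loss(fl, lpl)
      if (!is.finite(losses[bi]))
        stop("non-finite training loss at epoch ", epoch, ", batch ", bi,
             " (focal = ", fl, ", prototype = ", lpl, ")")
      grads <- net_backward(dz, dHp_extra, fwd, params, model_cfg, batch)
      upd <- adam_step(flat, flatten_grads(grads, dproto), state,
                       train_cfg$learning_rate, train_cfg$weight_decay)
      flat <- upd$flat
      state <- upd$state
      params <- unflatten_params(flat, params)
    }

    vf <- net_forward(val_X, params, model_cfg, val_batch,
                      val_batch$pool_sets, NULL)
    v_auprc <- auprc(vf$prob, val_y)
    v_auroc <- auroc(vf$prob, val_y)
    history[[epoch]] <- c(epoch = epoch, train_loss = mean(losses),
                          val_auprc = v_auprc, val_auroc = v_auroc)
    cur <- if (metric == "auprc") v_auprc else v_auroc
    if (cur > best$metric) {
      best <- list(metric = cur, flat = flat, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (verbose)
      message(sprintf("epoch %d  loss %.4f  val AUPRC %.4f  val AUROC %.4f",
                      epoch, mean(losses), v_auprc, v_auroc))
    if (stall >= train_cfg$patience) break
  }

  params <- unflatten_params(best$flat, params)
  vf <- net_forward(val_X, params, model_cfg, val_batch,
                    val_batch$pool_sets, NULL)
  thr <- youden_threshold(vf$prob, val_y)

  history <- as.data.frame(do.call(rbind, history[!vapply(history, is.null,
                                                          TRUE)]))
  structure(list(params = params, model = model_cfg, loss = loss_cfg,
                 train = train_cfg, metric = metric,
                 history = history, best_epoch = best$epoch,
                 val_metric = best$metric,
                 val_auprc = auprc(vf$prob, val_y),
                 val_auroc = auroc(vf$prob, val_y),
                 threshold = as.numeric(thr),
                 youden = attr(thr, "youden"),
                 graph = graph, no_edges = no_edges),
            class = "protogt")
}

#' Predict gene risk probabilities from a fitted model
#'
#' Runs the fitted encoder in evaluation mode (dropout disabled; the output
#' is deterministic) and returns per-gene positive-class probabilities with
#' the high-risk / low-risk call at the model's Youden threshold.
#'
#' @param object A fitted [protogt] model.
#' @param graph A `gene_graph`; defaults to the training graph
#'   (transductive prediction).
#' @param nodes Gene ids to score (default: all nodes).
#' @param threshold Decision threshold; defaults to the fitted Youden
#'   threshold.
#' @param ... Unused.
#' @return Data frame with columns `gene_id`, `probability`, `class`
#'   (`"HRG"` or `"LRG"`).
#' @export
predict.protogt <- function(object, graph = object$graph, nodes = NULL,
                            threshold = object$threshold, ...) {
  if (is.null(nodes)) nodes <- graph$node_ids
  idx <- match(nodes, graph$node_ids)
  if (anyNA(idx)) stop("unknown gene id in `nodes`")
  if (object$no_edges) graph$edges <- graph$edges[0L, , drop = FALSE]
  nb <- neighbor_list(graph)
  X <- graph$features
  probs <- numeric(length(idx))
  chunks <- split(seq_along(idx),
                  ceiling(seq_along(idx) / 256L))
  for (ch in chunks) {
    batch <- make_batch(graph, nb, idx[ch], object$model$pool)
    fwd <- net_forward(X[batch$nodes, , drop = FALSE], object$params,
                       object$model, batch, batch$pool_sets, NULL)
    probs[ch] <- fwd$prob
  }
  data.frame(gene_id = nodes, probability = probs,
             class = ifelse(probs >= threshold, "HRG", "LRG"),
             stringsAsFactors = FALSE)
}

#' @export
print.protogt <- function(x, ...) {
  cat("protogt graph-transformer gene classifier\n")
  cat(sprintf("  encoder: %d layers, hidden %d, %d heads, dropout %.2f, pool %s\n",
              x$model$n_layers, x$model$hidden_dim, x$model$n_heads,
              x$model$dropout, x$model$pool))
  cat(sprintf("  prototypes: %d per class (%d total)\n",
              x$model$prototypes_per_class,
              x$model$n_classes * x$model$prototypes_per_class))
  cat(sprintf("  trained %d epochs (best %d), val %s %.4f\n",
              nrow(x$history), x$best_epoch, toupper(x$metric),
              x$val_metric))
  cat(sprintf("  Youden threshold %.4f (J = %.4f)\n", x$threshold, x$youden))
  invisible(x)
}

#' @export
summary.protogt <- function(object, ...) {
  print(object)
  g <- object$graph
  cat(sprintf("  graph: %d nodes, %d edges, %d features\n",
              length(g$node_ids), nrow(g$edges), ncol(g$features)))
  cat(sprintf("  masks: %d train, %d val, %d test\n",
              sum(g$mask == "train"), sum(g$mask == "val"),
              sum(g$mask == "test")))
  cat(sprintf("  val AUROC %.4f, val AUPRC %.4f\n",
              object$val_auroc, object$val_auprc))
  invisible(object)
}

#' Extract fitted parameters
#'
#' @param object A fitted `protogt` model.
#' @param ... Unused.
#' @return Named list of parameter matrices; `proto` holds the prototype
#'   vectors (rows) with their classes in `proto_class`.
#' @export
coef.protogt <- function(object, ...) {
  c(flatten_params(object$params),
    list(proto_class = object$params$proto_class))
}

#' Plot the training history
#'
#' Training loss and validation metrics per epoch, with the selected
#' checkpoint marked.
#'
#' @param x A fitted `protogt` model.
#' @param ... Passed to [plot()].
#' @export
plot.protogt <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
       ylab = "training loss", main = "loss", ...)
  plot(h$epoch, h$val_auprc, type = "l", xlab = "epoch", ylab = "validation",
       ylim = range(c(h$val_auprc, h$val_auroc)), main = "validation")
  graphics::lines(h$epoch, h$val_auroc, lty = 2)
  graphics::abline(v = x$best_epoch, col = "grey60")
  graphics::legend("bottomright", c("AUPRC", "AUROC"), lty = 1:2, bty = "n")
  invisible(x)
}

#' Cross-validated fitting with best-fold selection
#'
#' Assigns the labeled training pool (mask `train` or `val`) to `k`
#' stratified folds, fits one model per fold with that fold as validation,
#' selects the fold with the best validation metric, and evaluates the
#' selected model on the hold-out test mask at its Youden threshold.
#'
#' @inheritParams protogt
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold assignment (per-fold training seeds are
#'   derived from the train config seed plus the fold index).
#' @return Object of class `protogt_cv`: `folds` (per-fold metrics),
#'   `best_fold`, `model` (the selected fit), and `test_eval`
#'   (a [evaluate_scores()] report on the test mask, or `NULL` if the graph
#'   has no test nodes).
#' @export
protogt_cv <- function(graph, k = 5L, model = NULL, loss = NULL,
                       train = NULL, metric = c("auprc", "auroc"),
                       no_edges = FALSE, seed = 0L, verbose = FALSE) {
  metric <- match.arg(metric)
  train_cfg <- resolve_config(train, pgt_train_config)
  y <- graph$labels
  pool <- graph$node_ids[graph$mask %in% c("train", "val") & !is.na(y)]
  folds <- kfold_assign(pool, y, k = k, seed = seed)
  fits <- vector("list", k)
  tab <- data.frame(fold = seq_len(k), val_auprc = NA_real_,
                    val_auroc = NA_real_, best_epoch = NA_integer_)
  for (f in seq_len(k)) {
    val_ids <- pool[folds == f]
    tr_ids <- setdiff(pool, val_ids)
    gf <- set_mask(graph, train = tr_ids, val = val_ids,
                   test = graph$node_ids[graph$mask == "test"])
    cfg_f <- train_cfg
    cfg_f$seed <- train_cfg$seed + f
    fits[[f]] <- protogt(gf, model = model, loss = loss, train = cfg_f,
                         metric = metric, no_edges = no_edges,
                         verbose = verbose)
    tab$val_auprc[f] <- fits[[f]]$val_auprc
    tab$val_auroc[f] <- fits[[f]]$val_auroc
    tab$best_epoch[f] <- fits[[f]]$best_epoch
  }
  sel <- if (metric == "auprc") which.max(tab$val_auprc)
         else which.max(tab$val_auroc)
  best_fit <- fits[[sel]]
  test_idx <- which(graph$mask == "test" & !is.na(y))
  test_eval <- NULL
  if (length(test_idx) && length(unique(y[test_idx])) == 2L) {
    pr <- predict(best_fit, nodes = graph$node_ids[test_idx])
    test_eval <- evaluate_scores(pr$probability, y[test_idx],
                                 threshold = best_fit$threshold,
                                 ids = pr$gene_id)
  }
  structure(list(folds = tab, best_fold = sel, model = best_fit,
                 test_eval = test_eval, metric = metric),
            class = "protogt_cv")
}

#' @export
print.protogt_cv <- function(x, ...) {
  cat(sprintf("protogt %d-fold cross-validation (metric %s)\n",
              nrow(x$folds), toupper(x$metric)))
  cat(sprintf("  val AUPRC %.4f +/- %.4f, val AUROC %.4f +/- %.4f\n",
              mean(x$folds$val_auprc), stats::sd(x$folds$val_auprc),
              mean(x$folds$val_auroc), stats::sd(x$folds$val_auroc)))
  cat(sprintf("  selected fold %d\n", x$best_fold))
  if (!is.null(x$test_eval)) {
    cat("  hold-out test: ")
    print(x$test_eval)
  }
  invisible(x)
}

#' Re-stamp train/val/test masks and refit preprocessing
#'
#' Assigns the given gene ids to the train, validation, and test masks and
#' refits the feature imputation and z-scoring on the new train-mask rows
#' only, using the raw (pre-preprocessing) feature matrix stored in the
#' graph.  Labeled genes not named fall back to mask `none`.
#'
#' @param graph A `gene_graph`.
#' @param train,val,test Character vectors of gene ids.
#' @return The updated `gene_graph`.
#' @export
set_mask <- function(graph, train, val = character(0), test = character(0)) {
  ids <- c(train, val, test)
  if (anyDuplicated(ids)) stop("train/val/test sets overlap")
  if (!all(ids %in% graph$node_ids)) stop("unknown gene id in mask sets")
  mask <- rep("none", length(graph$node_ids))
  names(mask) <- graph$node_ids
  mask[train] <- "train"; mask[val] <- "val"; mask[test] <- "test"
  graph$mask <- mask
  if (!is.null(graph$features_raw)) {
    pp <- fit_preprocess(graph$features_raw, which(mask == "train"))
    graph$features <- apply_preprocess(graph$features_raw, pp)
    graph$preprocess <- pp
  }
  graph
}
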