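#' Model architecture configuration
#'
#' Describes the graph-transformer encoder and the prototype layer.  The
#' encoder stacks `n_layers` multi-head attention layers restricted to graph
#' edges (edge weights enter as additive biases on the pre-softmax attention
#' scores), with layer normalization after each layer, an element-wise
#' max-pool readout over each center node's sampled neighborhood, dropout,
#' and a two-layer fully connected head emitting a single logit.  The
#' prototype layer holds `prototypes_per_class` learnable vectors per class
#' (`K = n_classes * prototypes_per_class` in total) in the same embedding
#' space as the pooled node representations.
#'
#' @param n_layers Number of graph-transformer layers (default 2).
#' @param hidden_dim Embedding width; must be divisible by `n_heads`.
#' @param n_heads Number of attention heads (default 4).
#' @param dropout Dropout probability applied to the pooled representation
#'   during training (default 0.4).
#' @param n_classes Number of classes `J` (binary task: 2).
#' @param prototypes_per_class Number of prototypes `M` allocated to each
#'   class (default 7).
#' @param pool Readout for a center node: `"neighborhood"` (element-wise max
#'   over the center and its first-order neighbors of the final-layer
#'   embeddings, the default) or `"subgraph"` (max over the center's full
#'   sampled two-hop subgraph).
#' @return An object of class `pgt_model_config`.
#' @export
pgt_model_config <- function(n_layers = 2L, hidden_dim = 64L, n_heads = 4L,
                             dropout = 0.4, n_classes = 2L,
                             prototypes_per_class = 7L,
                             pool = c("neighborhood", "subgraph")) {
  pool <- match.arg(pool)
  n_layers <- as.integer(n_layers)
  hidden_dim <- as.integer(hidden_dim)
  n_heads <- as.integer(n_heads)
  n_classes <- as.integer(n_classes)
  prototypes_per_class <- as.integer(prototypes_per_class)
  stopifnot(n_layers >= 1L, hidden_dim >= 1L, n_heads >= 1L,
            prototypes_per_class >= 1L, n_classes == 2L,
            dropout >= 0, dropout < 1)
  if (hidden_dim %% n_heads != 0L)
    stop("`hidden_dim` must be divisible by `n_heads`")
  structure(list(n_layers = n_layers, hidden_dim = hidden_dim,
                 n_heads = n_heads, dropout = dropout, n_classes = n_classes,
                 prototypes_per_class = prototypes_per_class, pool = pool),
            class = "pgt_model_config")
}

#' Loss configuration
#'
#' Hyperparameters of the combined objective: a prototype-contrastive term
#' at temperature `temperature` with distance-stabilizer `epsilon`, plus a
#' focal classification loss with weighting factor `focal_alpha` and
#' focusing parameter `focal_gamma`.
#'
#' @param temperature Softmax temperature `T` of the contrastive term
#'   (default 0.5).
#' @param epsilon Stabilizer in the prototype similarity
#'   `log((D + 1) / (D + epsilon))`; default 1e-4.
#' @param focal_alpha Class-weighting factor in `[0, 1]` (default 0.25).
#' @param focal_gamma Focusing exponent `>= 0` (default 2).
#' @param prototype_loss Logical; include the prototype-contrastive term
#'   (set `FALSE` for the ablation).
#' @param denominator Either `"other"` (the contrastive denominator runs
#'   over prototypes of the other classes only, the printed form) or
#'   `"all"` (InfoNCE-style denominator over every prototype).
#' @return An object of class `pgt_loss_config`.
#' @export
pgt_loss_config <- function(temperature = 0.5, epsilon = 1e-4,
                            focal_alpha = 0.25, focal_gamma = 2,
                            prototype_loss = TRUE,
                            denominator = c("other", "all")) {
  denominator <- match.arg(denominator)
  stopifnot(temperature > 0, epsilon > 0, epsilon <= 1,
            focal_alpha >= 0, focal_alpha <= 1, focal_gamma >= 0,
            is.logical(prototype_loss), length(prototype_loss) == 1L)
  structure(list(temperature = temperature, epsilon = epsilon,
                 focal_alpha = focal_alpha, focal_gamma = focal_gamma,
                 prototype_loss = prototype_loss, denominator = denominator),
            class = "pgt_loss_config")
}

#' Training configuration
#'
#' @param max_epochs Upper bound on training epochs (default 500).
#' @param patience Early-stopping patience: training stops once the
#'   validation metric has not improved for this many consecutive epochs
#'   (default 50).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param weight_decay L2 penalty applied to weight matrices (default 5e-4).
#' @param batch_size Number of center nodes per mini-batch (default 64).
#' @param seed Integer seed controlling initialization, batching, and
#'   dropout.
#' @return An object of class `pgt_train_config`.
#' @export
pgt_train_config <- function(max_epochs = 500L, patience = 50L,
                             learning_rate = 1e-3, weight_decay = 5e-4,
                             batch_size = 64L, seed = 0L) {
  max_epochs <- as.integer(max_epochs)
  patience <- as.integer(patience)
  batch_size <- as.integer(batch_size)
  stopifnot(max_epochs >= 1L, patience >= 1L, patience <= max_epochs,
            learning_rate > 0, weight_decay >= 0, batch_size >= 1L)
  structure(list(max_epochs = max_epochs, patience = patience,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = batch_size, seed = as.integer(seed)),
            class = "pgt_train_config")
}

# resolve a config argument that may be a list of overrides
resolve_config <- function(x, constructor) {
  if (inherits(x, class(constructor())[1L])) return(x)
  if (is.null(x)) return(constructor())
  if (is.list(x)) return(do.call(constructor, x))
  stop("invalid configuration object")
}
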