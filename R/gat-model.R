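#' Configuration for the graph-attention classifier
#'
#' Hyperparameters of the activity classifier. The defaults suit the small
#' dataset regime this model is built for (tens to a few hundred labeled
#' compounds).
#'
#' @param n_gat_layers number of graph-attention convolution layers.
#' @param hidden_dim node embedding width (must be divisible by
#'   \code{n_attention_heads}).
#' @param n_attention_heads attention heads, shared by the GAT layers and the
#'   self-attention layer.
#' @param dropout dropout probability in [0, 1) applied to node embeddings
#'   between layers and to the fully connected hidden layer during training.
#' @param learning_rate Adam step size.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience on validation loss (epochs).
#' @param class_weighting use inverse-frequency class weights in the loss.
#' @param seed integer seed governing initialization, dropout and shuffling.
#' @param pretrained_state optional trunk parameters from
#'   \code{\link{pretrainLogP}} used to initialize the message-passing trunk.
#' @return a named list of class \code{gat_config}.
#' @export
gatConfig <- function(n_gat_layers = 3L, hidden_dim = 64L,
                      n_attention_heads = 4L, dropout = 0.2,
                      learning_rate = 1e-3, max_epochs = 300L,
                      patience = 30L, class_weighting = TRUE, seed = 1L,
                      pretrained_state = NULL) {
  stopifnot(n_gat_layers >= 1, hidden_dim >= 1, n_attention_heads >= 1,
            dropout >= 0, dropout < 1, learning_rate > 0, max_epochs >= 1,
            patience >= 1)
  if (hidden_dim %% n_attention_heads != 0) {
    stop("hidden_dim must be divisible by n_attention_heads")
  }
  structure(list(n_gat_layers = as.integer(n_gat_layers),
                 hidden_dim = as.integer(hidden_dim),
                 n_attention_heads = as.integer(n_attention_heads),
                 dropout = dropout, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 class_weighting = isTRUE(class_weighting),
                 seed = as.integer(seed),
                 pretrained_state = pretrained_state),
            class = "gat_config")
}

#' Build an (untrained) graph-attention classifier
#'
#' Constructs the model: a stack of graph-attention convolution layers for
#' message passing, one multi-head self-attention layer over node embeddings
#' (with residual connection), a readout concatenating global max pooling and
#' global mean pooling, and two fully connected layers producing a single
#' activity logit. Parameter initialization is deterministic under the
#' configuration seed. When \code{pretrained_state} is set, the trunk (GAT
#' stack + self-attention) starts from those weights and only the head is
#' freshly initialized.
#'
#' @param config a \code{gat_config} from \code{\link{gatConfig}}.
#' @param featureMeta feature layout of the training data; defaults to the
#'   package's current featurization (taken from any
#'   \linkS4class{MoleculeGraph} metadata).
#' @return a \linkS4class{GatModel}.
#' @export
buildGatModel <- function(config = gatConfig(), featureMeta = NULL) {
  if (is.null(featureMeta)) {
    featureMeta <- list(feature_version = FEATURE_VERSION,
                        node_dim = length(node_feature_names()),
                        edge_dim = length(edge_feature_names()))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  fin <- featureMeta$node_dim
  H <- config$hidden_dim
  heads <- config$n_attention_heads
  gat <- vector("list", config$n_gat_layers)
  for (l in seq_len(config$n_gat_layers)) {
    gat[[l]] <- gat_init(if (l == 1) fin else H, H, heads, featureMeta$edge_dim)
  }
  params <- list(gat = gat, mhsa = mhsa_init(H, heads), fc = fc_init(2 * H, H))
  if (!is.null(config$pretrained_state)) {
    ps <- config$pretrained_state
    if (!identical(ps$feature_version, featureMeta$feature_version)) {
      stop("pretrained state was built for feature set ",
           ps$feature_version %||% "<unknown>", ", dataset uses ",
           featureMeta$feature_version)
    }
    params$gat <- ps$trunk$gat
    params$mhsa <- ps$trunk$mhsa
  }
  new("GatModel", config = unclass(config), params = params,
      featureMeta = featureMeta, trained = FALSE,
      history = data.frame())
}

# Full forward pass on a batch. `training` enables dropout (masks drawn from
# the current RNG stream); keep_attention stores per-graph attention matrices.
gat_model_forward <- function(params, config, batch, training = FALSE,
                              keep_attention = FALSE) {
  X <- batch$X
  if (ncol(X) != nrow(params$gat[[1]]$W)) {
    stop("feature dimension mismatch: batch has ", ncol(X),
         " node features, model expects ", nrow(params$gat[[1]]$W))
  }
  L <- length(params$gat)
  caches <- list(gat = vector("list", L), drop = vector("list", L),
                 layer_in = vector("list", L))
  for (l in seq_len(L)) {
    caches$layer_in[[l]] <- X
    r <- gat_forward(params$gat[[l]], X, batch$edges, batch$efeat, batch$N)
    X <- r$out
    if (training && config$dropout > 0) {
      mask <- matrix(stats::rbinom(length(X), 1, 1 - config$dropout),
                     nrow(X), ncol(X)) / (1 - config$dropout)
      X <- X * mask
      caches$drop[[l]] <- mask
    }
    caches$gat[[l]] <- r$cache
  }
  rm_ <- mhsa_forward(params$mhsa, X, batch$node_idx, config$n_attention_heads,
                      keep_attention = keep_attention)
  caches$mhsa <- rm_$cache
  caches$X_mhsa_in <- X
  pf <- pool_forward(rm_$out, batch$node_idx)
  caches$pool <- pf
  caches$X_pool_in <- rm_$out
  fc_mask <- NULL
  if (training && config$dropout > 0) {
    fc_mask <- matrix(stats::rbinom(batch$n_graphs * config$hidden_dim, 1,
                                    1 - config$dropout),
                      batch$n_graphs, config$hidden_dim) / (1 - config$dropout)
  }
  fr <- fc_forward(params$fc, pf$out, drop_mask = fc_mask)
  caches$fc <- fr$cache
  list(logits = drop(fr$out), caches = caches, attention = rm_$attention)
}

gat_model_backward <- function(params, config, batch, caches, dlogits) {
  fb <- fc_backward(params$fc, dlogits, caches$fc)
  dXp <- pool_backward(fb$dU, caches$X_pool_in, batch$node_idx,
                       caches$pool$argmax)
  mb <- mhsa_backward(params$mhsa, dXp, caches$X_mhsa_in, batch$node_idx,
                      config$n_attention_heads, caches$mhsa)
  dX <- mb$dX
  ggat <- vector("list", length(params$gat))
  for (l in rev(seq_along(params$gat))) {
    if (!is.null(caches$drop[[l]])) dX <- dX * caches$drop[[l]]
    gb <- gat_backward(params$gat[[l]], dX, caches$layer_in[[l]], batch$edges,
                       batch$efeat, batch$N, caches$gat[[l]])
    dX <- gb$dX
    ggat[[l]] <- gb$grads
  }
  list(grads = list(gat = ggat, mhsa = mb$grads, fc = fb$grads))
}
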