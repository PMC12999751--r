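# Training, pretraining and repeat-averaged evaluation of the classifier.

partition_indices <- function(dataset, assignment) {
  grp <- dataset@groupIds
  unknown <- setdiff(unique(grp), names(assignment))
  if (length(unknown) > 0) {
    stop("dataset contains groups missing from the split assignment: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  part <- assignment[grp]
  lapply(c(train = "train", validation = "validation", test = "test"),
         function(p) which(part == p))
}

#' Train the graph-attention classifier on one split repeat
#'
#' Minimizes class-weighted binary cross-entropy with full-batch Adam, with
#' early stopping on validation loss: training halts once the validation loss
#' has not improved for \code{patience} epochs and the parameters of the best
#' validation epoch are restored. All randomness (dropout, initialization if
#' the model is rebuilt) is governed by the configuration seed, so a repeated
#' run reproduces the run exactly.
#'
#' @param model a \linkS4class{GatModel} (untrained or to be fine-tuned).
#' @param dataset a \linkS4class{GraphDataset}.
#' @param assignment named character vector mapping every group id of the
#'   dataset to \code{"train"}, \code{"validation"} or \code{"test"} — one
#'   repeat of a \linkS4class{SplitPlan} (see \code{\link{assignments}}).
#' @param verbose print per-epoch progress.
#' @return the trained \linkS4class{GatModel}; the per-epoch log is in
#'   \code{@history}.
#' @export
trainGat <- function(model, dataset, assignment, verbose = FALSE) {
  stopifnot(is(model, "GatModel"), is(dataset, "GraphDataset"))
  config <- model@config
  idx <- partition_indices(dataset, assignment)
  if (length(idx$train) == 0 || length(idx$validation) == 0) {
    stop("empty train or validation partition")
  }
  y <- dataset@labels
  tr_batch <- build_batch(dataset@graphs[idx$train], y[idx$train])
  va_batch <- build_batch(dataset@graphs[idx$validation], y[idx$validation])

  w <- rep(1, length(idx$train))
  if (config$class_weighting) {
    n1 <- sum(tr_batch$y == 1); n0 <- sum(tr_batch$y == 0)
    if (n1 > 0 && n0 > 0) {
      w <- ifelse(tr_batch$y == 1, length(w) / (2 * n1), length(w) / (2 * n0))
    }
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  params <- model@params
  opt <- adam_init(params)
  best <- list(val = Inf, params = params, epoch = 0L)
  hist <- vector("list", config$max_epochs)
  stale <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    fw <- gat_model_forward(params, config, tr_batch, training = TRUE)
    lo <- bce_loss(fw$logits, tr_batch$y, w)
    if (!is.finite(lo$loss)) {
      stop("non-finite training loss at epoch ", epoch,
           " (learning rate too high or degenerate input)")
    }
    bw <- gat_model_backward(params, config, tr_batch, fw$caches, lo$dz)
    st <- adam_step(params, bw$grads, opt, config$learning_rate)
    params <- st$params; opt <- st$state

    vf <- gat_model_forward(params, config, va_batch, training = FALSE)
    vl <- bce_loss(vf$logits, va_batch$y, rep(1, va_batch$n_graphs))
    tr_acc <- mean((fw$logits > 0) == (tr_batch$y == 1))
    va_acc <- mean((vf$logits > 0) == (va_batch$y == 1))
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = lo$loss,
                                train_accuracy = tr_acc,
                                val_loss = vl$loss, val_accuracy = va_acc)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f (acc %.3f)  val %.4f (acc %.3f)",
                      epoch, lo$loss, tr_acc, vl$loss, va_acc))
    }
    if (vl$loss < best$val - 1e-6) {
      best <- list(val = vl$loss, params = params, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }

  out <- model
  out@params <- best$params
  out@trained <- TRUE
  out@history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  attr(out@history, "best_epoch") <- best$epoch
  out
}

#' Train one model per split repeat
#'
#' @param dataset a \linkS4class{GraphDataset}.
#' @param plan a \linkS4class{SplitPlan}.
#' @param config a \code{gat_config}; the per-repeat seed is derived from
#'   \code{config$seed} + repeat index so repeats are independent but
#'   reproducible.
#' @param verbose print progress.
#' @return list of trained \linkS4class{GatModel}s, one per repeat.
#' @export
trainRepeats <- function(dataset, plan, config = gatConfig(), verbose = FALSE) {
  lapply(seq_len(plan@nRepeats), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r
    model <- buildGatModel(cfg)
    trainGat(model, dataset, assignments(plan, r), verbose = verbose)
  })
}

#' Evaluate trained models over split repeats
#'
#' Computes test-partition accuracy (decision threshold 0.5 on the predicted
#' probability), sensitivity, specificity and confusion counts per repeat,
#' and their mean and standard deviation across repeats.
#'
#' @param models list of trained \linkS4class{GatModel}s, one per repeat of
#'   \code{plan}.
#' @param dataset the \linkS4class{GraphDataset} the plan refers to.
#' @param plan the \linkS4class{SplitPlan}.
#' @param partition which partition to score (default \code{"test"}).
#' @return an \linkS4class{EvalReport}.
#' @export
evaluateRepeats <- function(models, dataset, plan, partition = "test") {
  stopifnot(length(models) == plan@nRepeats)
  rows <- lapply(seq_along(models), function(r) {
    idx <- partition_indices(dataset, assignments(plan, r))[[partition]]
    if (length(idx) == 0) stop("empty ", partition, " partition in repeat ", r)
    prob <- predict_graphs(models[[r]], dataset@graphs[idx])
    pred <- as.integer(prob >= 0.5)
    truth <- dataset@labels[idx]
    tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
    fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
    data.frame(repeat_index = r, accuracy = (tp + tn) / length(idx),
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               tp = tp, fp = fp, tn = tn, fn = fn, n = length(idx))
  })
  per <- do.call(rbind, rows)
  new("EvalReport", perRepeat = per, meanAccuracy = mean(per$accuracy),
      sdAccuracy = stats::sd(per$accuracy), nRepeats = plan@nRepeats)
}

predict_graphs <- function(model, graphs) {
  batch <- build_batch(graphs)
  fw <- gat_model_forward(model@params, model@config, batch, training = FALSE)
  sigmoid(fw$logits)
}

#' Predict inhibition activity for molecules
#'
#' Canonicalizes and featurizes the input SMILES and returns the model's
#' predicted probability of nitrification-inhibition activity and the binary
#' class at threshold 0.5. Inference is deterministic; two spellings of the
#' same molecule receive the same prediction.
#'
#' @param model a trained \linkS4class{GatModel}.
#' @param smiles character vector of SMILES.
#' @return data.frame with columns \code{smiles} (canonical),
#'   \code{probability} and \code{class}.
#' @export
predictActivity <- function(model, smiles) {
  stopifnot(is(model, "GatModel"))
  graphs <- lapply(smiles, featurizeSmiles)
  prob <- predict_graphs(model, graphs)
  data.frame(smiles = vapply(graphs, function(g) g@smiles, character(1)),
             probability = prob,
             class = as.integer(prob >= 0.5),
             stringsAsFactors = FALSE)
}

# ---- log P pretraining -----------------------------------------------------

# additive per-atom lipophilicity contributions (fragment-style surrogate)
LOGP_CONTRIB <- c(C_aromatic = 0.30, C = 0.20, N = -0.60, O = -0.45,
                  S = 0.25, P = -0.50, F = 0.35, Cl = 0.55, Br = 0.70,
                  I = 0.80, other = 0)

additive_logp <- function(graph) {
  nf <- graph@nodeFeatures
  el <- graph@metadata$elements
  contrib <- LOGP_CONTRIB[ifelse(el %in% names(LOGP_CONTRIB), el, "other")]
  arom <- nf[, "aromatic"] == 1 & el == "C"
  contrib[arom] <- LOGP_CONTRIB["C_aromatic"]
  sum(contrib) + 0.1 * sum(nf[, "h_count"][el == "C"])
}

#' Synthetic lipophilicity pretraining corpus
#'
#' Generates decorated molecules and their additive-fragment lipophilicity
#' scores (a fixed per-atom contribution table), a mechanistically relevant
#' but fully synthetic regression surrogate used to pretrain the classifier
#' trunk before fine-tuning on inhibition labels.
#'
#' @param n_molecules corpus size.
#' @param seed integer seed.
#' @return list with \code{graphs} (list of \linkS4class{MoleculeGraph}) and
#'   \code{values} (numeric lipophilicity scores).
#' @export
makeLogPSurrogate <- function(n_molecules = 200L, seed = 1L) {
  d <- generateSarDataset(sarSimParams(n_compounds = n_molecules,
                                       label_noise = 0, seed = seed))
  graphs <- lapply(d$smiles, featurizeSmiles)
  list(graphs = graphs, values = vapply(graphs, additive_logp, numeric(1)))
}

#' Pretrain the model trunk on a lipophilicity surrogate
#'
#' Trains the message-passing trunk (GAT stack + self-attention + pooling)
#' with a fresh regression head on (graph, lipophilicity) pairs by full-batch
#' Adam on mean squared error, and returns the trunk weights for transfer.
#' Fine-tuning builds a new model from these weights
#' (\code{gatConfig(pretrained_state = ...)}), which re-initializes the
#' classification head while keeping the trunk.
#'
#' @param model an untrained \linkS4class{GatModel} defining the architecture.
#' @param surrogate a corpus from \code{\link{makeLogPSurrogate}}.
#' @param epochs pretraining epochs (no early stopping; the surrogate has no
#'   validation split).
#' @param learning_rate Adam step size (defaults to the model's).
#' @return a pretrained-state list (\code{trunk}, \code{feature_version},
#'   \code{history}) for \code{\link{gatConfig}}.
#' @export
pretrainLogP <- function(model, surrogate, epochs = 60L, learning_rate = NULL) {
  stopifnot(is(model, "GatModel"))
  config <- model@config
  if (!is.null(learning_rate)) config$learning_rate <- learning_rate
  batch <- build_batch(surrogate$graphs)
  y <- surrogate$values
  sdy <- stats::sd(y); muy <- mean(y)
  yz <- (y - muy) / ifelse(sdy > 0, sdy, 1)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed + 10000L)

  params <- model@params
  params$fc <- fc_init(2 * config$hidden_dim, config$hidden_dim)  # regression head
  opt <- adam_init(params)
  hist <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    fw <- gat_model_forward(params, config, batch, training = TRUE)
    res <- fw$logits - yz
    loss <- mean(res^2)
    if (!is.finite(loss)) stop("non-finite pretraining loss at epoch ", epoch)
    hist[epoch] <- loss
    bw <- gat_model_backward(params, config, batch, fw$caches,
                             2 * res / length(res))
    st <- adam_step(params, bw$grads, opt, config$learning_rate)
    params <- st$params; opt <- st$state
  }
  list(trunk = list(gat = params$gat, mhsa = params$mhsa),
       feature_version = model@featureMeta$feature_version,
       target_moments = c(mean = muy, sd = sdy),
       history = data.frame(epoch = seq_len(epochs), loss = hist))
}
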