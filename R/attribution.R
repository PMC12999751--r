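# Model explanation: corrected attention weights per atom and Shapley values
# per matched substructure.

#' Per-atom attention saliency
#'
#' Extracts the attention matrices of the multi-head self-attention layer for
#' one molecule and corrects them into a single per-atom saliency: the
#' per-head row-stochastic attention matrices are averaged over heads, the
#' attention each atom receives is averaged over querying atoms (column
#' means), and the resulting vector is normalized to sum to one. The
#' correction is isolated here so alternative schemes can be swapped in.
#'
#' @param model a trained \linkS4class{GatModel}.
#' @param smiles a single SMILES string.
#' @return numeric vector of nonnegative per-atom weights summing to 1, in
#'   canonical atom order.
#' @export
attentionAtomWeights <- function(model, smiles) {
  stopifnot(is(model, "GatModel"))
  if (is.null(model@params$mhsa)) stop("model has no attention layer")
  graph <- if (is(smiles, "MoleculeGraph")) smiles else featurizeSmiles(smiles)
  batch <- build_batch(list(graph))
  fw <- gat_model_forward(model@params, model@config, batch, training = FALSE,
                          keep_attention = TRUE)
  heads <- fw$attention[[1]]
  A <- Reduce(`+`, heads) / length(heads)
  w <- colMeans(A)
  w <- pmax(w, 0)
  w / sum(w)
}

# value function for Shapley: model probability with the complement of a
# coalition masked (node features of atoms belonging to absent players zeroed;
# atoms outside every player -- the scaffold -- stay visible).
shapley_values_batch <- function(model, graph, player_atoms, subsets) {
  base_nf <- graph@nodeFeatures
  graphs <- lapply(subsets, function(s) {
    masked <- unique(unlist(player_atoms[!seq_along(player_atoms) %in% s]))
    # atoms in an absent player but shared with a present player stay visible
    present <- unique(unlist(player_atoms[s]))
    masked <- setdiff(masked, present)
    g <- graph
    if (length(masked) > 0) g@nodeFeatures[masked, ] <- 0
    g
  })
  probs <- numeric(length(graphs))
  chunk <- 256L
  for (st in seq(1, length(graphs), by = chunk)) {
    ix <- st:min(st + chunk - 1L, length(graphs))
    probs[ix] <- predict_graphs(model, graphs[ix])
  }
  probs
}

#' Shapley attribution of substructure instances
#'
#' Treats each matched instance of the supplied substructure patterns as a
#' player in a cooperative game whose value is the model's predicted
#' probability with all absent players' atoms feature-masked (graph topology
#' is kept; only node features are zeroed, avoiding message-passing artifacts
#' from deleted nodes). Returns the exact Shapley value of every instance
#' when the number of players \code{m} is at most \code{exact_max}
#' (enumerating all \code{2^m} coalitions), and a Monte-Carlo permutation
#' estimate otherwise. Values satisfy the efficiency axiom: they sum to the
#' prediction of the intact molecule minus the prediction of the fully masked
#' baseline.
#'
#' Patterns with no match are dropped with a warning. Overlapping instances
#' are allowed; an atom shared by a present and an absent player stays
#' visible.
#'
#' @param model a trained \linkS4class{GatModel}.
#' @param smiles a single SMILES string.
#' @param patterns named list of \code{bni_pattern}s (default
#'   \code{\link{alertPatterns}()}).
#' @param n_samples Monte-Carlo permutations (used only when
#'   \code{m > exact_max}); must be at least \code{10 * m}.
#' @param seed integer seed for Monte-Carlo sampling.
#' @param exact_max largest player count for exact enumeration (default 12).
#' @return named numeric vector of Shapley values (one per instance; names
#'   are pattern names, suffixed \code{#k} for multiple instances), with
#'   attributes \code{full} (intact prediction), \code{baseline} (all-masked
#'   prediction), \code{atoms} (matched atom sets) and \code{method}.
#' @export
shapleySubstructures <- function(model, smiles, patterns = alertPatterns(),
                                 n_samples = 2000L, seed = 1L,
                                 exact_max = 12L) {
  stopifnot(is(model, "GatModel"))
  graph <- if (is(smiles, "MoleculeGraph")) smiles else featurizeSmiles(smiles)
  if (is.null(names(patterns))) {
    names(patterns) <- vapply(patterns, function(p) p$name, character(1))
  }

  player_atoms <- list()
  for (pn in names(patterns)) {
    inst <- matchSubstructure(graph@smiles, patterns[[pn]])
    if (length(inst) == 0) next
    for (k in seq_along(inst)) {
      nm <- if (length(inst) == 1) pn else paste0(pn, "#", k)
      player_atoms[[nm]] <- sort(unique(inst[[k]]))
    }
  }
  dropped <- setdiff(names(patterns),
                     sub("#[0-9]+$", "", names(player_atoms)))
  if (length(dropped) > 0) {
    warning("pattern(s) with no match excluded: ",
            paste(dropped, collapse = ", "))
  }
  m <- length(player_atoms)
  full <- as.numeric(predict_graphs(model, list(graph)))
  if (m == 0) {
    out <- numeric(0)
    attr(out, "full") <- full; attr(out, "baseline") <- full
    attr(out, "atoms") <- list(); attr(out, "method") <- "none"
    return(out)
  }

  if (m <= exact_max) {
    subsets <- lapply(0:(2^m - 1), function(msk) which(bitwAnd(msk, 2^(0:(m - 1))) > 0))
    v <- shapley_values_batch(model, graph, player_atoms, subsets)
    names(v) <- vapply(subsets, function(s) paste(s, collapse = ","), character(1))
    fact <- factorial(0:m)
    phi <- numeric(m)
    for (i in seq_len(m)) {
      for (k in seq_along(subsets)) {
        s <- subsets[[k]]
        if (i %in% s) next
        key_with <- paste(sort(c(s, i)), collapse = ",")
        wgt <- fact[length(s) + 1] * fact[m - length(s)] / fact[m + 1]
        phi[i] <- phi[i] + wgt * (v[[key_with]] - v[[k]])
      }
    }
    method <- "exact"
    baseline <- v[[1]]
  } else {
    if (n_samples < 10 * m) {
      stop("n_samples must be at least 10 * m (= ", 10 * m,
           ") in Monte-Carlo mode")
    }
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(as.integer(seed))
    perms <- replicate(n_samples, sample.int(m), simplify = FALSE)
    # evaluate the distinct prefix coalitions of the sampled permutations
    subsets <- list(integer(0))
    need <- new.env(parent = emptyenv())
    need[["k"]] <- 1L
    for (p in perms) {
      for (j in seq_len(m)) {
        key <- paste0("k", paste(sort(p[1:j]), collapse = ","))
        if (is.null(need[[key]])) {
          subsets[[length(subsets) + 1L]] <- sort(p[1:j])
          need[[key]] <- length(subsets)
        }
      }
    }
    v <- shapley_values_batch(model, graph, player_atoms, subsets)
    lookup <- function(s) v[need[[paste0("k", paste(s, collapse = ","))]]]
    phi <- numeric(m)
    for (p in perms) {
      prev <- lookup(integer(0))
      for (j in seq_len(m)) {
        cur <- lookup(sort(p[1:j]))
        phi[p[j]] <- phi[p[j]] + (cur - prev)
        prev <- cur
      }
    }
    phi <- phi / n_samples
    method <- "monte_carlo"
    baseline <- v[1]
  }
  names(phi) <- names(player_atoms)
  attr(phi, "full") <- full
  attr(phi, "baseline") <- as.numeric(baseline)
  attr(phi, "atoms") <- player_atoms
  attr(phi, "method") <- method
  phi
}

#' Full attribution of one molecule
#'
#' Combines the prediction, the corrected attention atom weights and
#' per-pattern Shapley values (instances of the same pattern summed) into an
#' \linkS4class{AttributionMap}.
#'
#' @inheritParams shapleySubstructures
#' @return an \linkS4class{AttributionMap}.
#' @export
attributeMolecule <- function(model, smiles, patterns = alertPatterns(),
                              n_samples = 2000L, seed = 1L, exact_max = 12L) {
  graph <- if (is(smiles, "MoleculeGraph")) smiles else featurizeSmiles(smiles)
  w <- attentionAtomWeights(model, graph)
  phi <- suppressWarnings(
    shapleySubstructures(model, graph, patterns, n_samples, seed, exact_max)
  )
  base <- sub("#[0-9]+$", "", names(phi))
  agg <- if (length(phi) > 0) tapply(as.numeric(phi), base, sum) else numeric(0)
  new("AttributionMap", smiles = graph@smiles, atomWeights = w,
      substructureValues = as.numeric(agg) |> stats::setNames(names(agg)),
      prediction = attr(phi, "full"))
}

#' Rank substructures by aggregate Shapley contribution
#'
#' Aggregates per-pattern Shapley values over the predicted positives of a
#' collection of attribution maps (mean value per pattern) and returns the
#' ranked structural-alert table.
#'
#' @param attributions list of \linkS4class{AttributionMap}s.
#' @param top_k number of rows to keep (default: all).
#' @param threshold probability threshold defining predicted positives.
#' @return data.frame with columns \code{pattern}, \code{mean_value},
#'   \code{n_molecules}, sorted by decreasing mean value.
#' @export
reportStructuralAlerts <- function(attributions, top_k = Inf, threshold = 0.5) {
  stopifnot(length(attributions) >= 1)
  pos <- Filter(function(a) a@prediction >= threshold, attributions)
  if (length(pos) == 0) pos <- attributions
  vals <- list()
  for (a in pos) {
    for (pn in names(a@substructureValues)) {
      vals[[pn]] <- c(vals[[pn]], a@substructureValues[[pn]])
    }
  }
  out <- data.frame(
    pattern = names(vals),
    mean_value = vapply(vals, mean, numeric(1)),
    n_molecules = vapply(vals, length, integer(1)),
    row.names = NULL
  )
  out <- out[order(-out$mean_value), ]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

#' Write per-molecule attributions as JSON
#'
#' @param attributions list of \linkS4class{AttributionMap}s.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeAttributions <- function(attributions, path) {
  obj <- lapply(attributions, function(a) {
    list(smiles = a@smiles, prediction = a@prediction,
         atom_weights = as.list(stats::setNames(a@atomWeights,
                                                seq_along(a@atomWeights))),
         substructure_values = as.list(a@substructureValues))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
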