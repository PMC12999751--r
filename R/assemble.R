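#' Assemble a labeled graph dataset, optionally tautomer-augmented
#'
#' Converts labeled compound records into the \linkS4class{GraphDataset}
#' consumed by the classifier. With \code{augment = TRUE} every compound is
#' expanded to its tautomer group under the given rule set, each member
#' inheriting the parent's label and group id (the leakage key). A manifest
#' records example counts before and after augmentation per class, the rule
#' set version, and any cross-parent duplicate tautomers; duplicates are
#' resolved to the first parent with a warning rather than failing, since
#' real libraries do contain shared tautomers.
#'
#' @param records data.frame with columns \code{id}, \code{smiles} and
#'   \code{label} (0/1); typically from \code{\link{generateSarDataset}} or
#'   \code{\link{readCompoundTable}} + \code{\link{labelFromEc50}}.
#' @param augment expand each compound to its tautomer group.
#' @param rules tautomer rule set (see \code{\link{tautomerRules}}).
#' @param cap maximum tautomers per compound.
#' @param steps rewrite passes for enumeration.
#' @return a \linkS4class{GraphDataset}.
#' @examples
#' recs <- data.frame(id = "a", smiles = "CC(C)=O", label = 1L)
#' length(assembleDataset(recs, augment = TRUE))  # acetone + its enol
#' @export
assembleDataset <- function(records, augment = FALSE, rules = tautomerRules(),
                            cap = 32L, steps = 1L) {
  stopifnot(is.data.frame(records),
            all(c("id", "smiles", "label") %in% names(records)))
  if (any(is.na(records$label))) stop("all records must be labeled")
  if (anyDuplicated(records$id)) stop("record ids must be unique")

  smiles_list <- list()
  label_list <- list()
  group_list <- list()
  collisions <- list()

  for (k in seq_len(nrow(records))) {
    id <- records$id[k]
    lab <- as.integer(records$label[k])
    mem <- if (augment) {
      members(enumerateTautomers(records$smiles[k], rules = rules, cap = cap,
                                 steps = steps, parentId = id, label = lab))
    } else {
      canonicalizeSmiles(records$smiles[k])
    }
    smiles_list[[k]] <- mem
    label_list[[k]] <- rep(lab, length(mem))
    group_list[[k]] <- rep(id, length(mem))
  }
  smi <- unlist(smiles_list)
  lab <- unlist(label_list)
  grp <- unlist(group_list)

  dup <- duplicated(smi)
  if (any(dup)) {
    for (s in unique(smi[dup])) {
      owners <- unique(grp[smi == s])
      if (length(owners) > 1) {
        collisions[[length(collisions) + 1L]] <-
          list(smiles = s, parents = owners, resolved_to = owners[1])
      }
    }
    if (length(collisions) > 0) {
      warning(length(collisions),
              " canonical SMILES shared across parents; membership resolved ",
              "to the first parent (see manifest$collisions)")
    }
    keep <- !dup
    smi <- smi[keep]; lab <- lab[keep]; grp <- grp[keep]
  }

  graphs <- lapply(smi, function(s) molgraph_to_molecule_graph(parse_molgraph(s)))

  manifest <- list(
    augment = augment,
    rules_version = attr(rules, "version"),
    cap = as.integer(cap),
    steps = as.integer(steps),
    n_before = nrow(records),
    n_after = length(smi),
    n_before_by_class = as.list(table(factor(records$label, levels = c(0, 1)))),
    n_after_by_class = as.list(table(factor(lab, levels = c(0, 1)))),
    collisions = collisions
  )
  new("GraphDataset", graphs = graphs, smiles = smi, labels = lab,
      groupIds = grp, manifest = manifest)
}
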