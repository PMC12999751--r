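#' @rdname MoleculeGraph-class
#' @export
setMethod("nodeFeatures", "MoleculeGraph", function(x) x@nodeFeatures)

#' @rdname MoleculeGraph-class
#' @export
setMethod("edgeList", "MoleculeGraph", function(x) x@edgeList)

#' @rdname MoleculeGraph-class
#' @export
setMethod("edgeFeatures", "MoleculeGraph", function(x) x@edgeFeatures)

#' @rdname MoleculeGraph-class
#' @export
setMethod("smiles", "MoleculeGraph", function(x) x@smiles)

#' @rdname GraphDataset-class
#' @export
setMethod("smiles", "GraphDataset", function(x) x@smiles)

#' @rdname MoleculeGraph-class
#' @export
setMethod("show", "MoleculeGraph", function(object) {
  cat("MoleculeGraph:", object@smiles, "\n")
  cat(" ", nrow(object@nodeFeatures), "atoms,", nrow(object@edgeList),
      "directed edges, feature set",
      object@metadata$feature_version %||% "?", "\n")
})

#' @rdname TautomerGroup-class
#' @export
setMethod("members", "TautomerGroup", function(x) x@members)

#' @rdname TautomerGroup-class
#' @export
setMethod("parentId", "TautomerGroup", function(x) x@parentId)

#' @rdname TautomerGroup-class
#' @export
setMethod("datasetLabels", "TautomerGroup", function(x) x@label)

#' @rdname TautomerGroup-class
#' @export
setMethod("show", "TautomerGroup", function(object) {
  cat("TautomerGroup", sQuote(object@parentId), "with",
      length(object@members), "member(s); label:", object@label, "\n")
  cat("  parent:", object@members[1], "\n")
})

#' @rdname SplitPlan-class
#' @export
setMethod("assignments", "SplitPlan", function(x, repeatIndex = 1L) {
  stopifnot(repeatIndex >= 1L, repeatIndex <= x@nRepeats)
  x@assignments[[repeatIndex]]
})

#' @rdname SplitPlan-class
#' @export
setMethod("show", "SplitPlan", function(object) {
  cat("SplitPlan:", object@nRepeats, "repeat(s) over",
      length(object@assignments[[1]]), "groups; fractions",
      paste(sprintf("%s=%.2f", c("train", "validation", "test"),
                    object@fractions), collapse = ", "),
      "; seed", object@seed, "\n")
})

#' @rdname GraphDataset-class
#' @export
setMethod("datasetLabels", "GraphDataset", function(x) x@labels)

#' @rdname GraphDataset-class
#' @export
setMethod("groupIds", "GraphDataset", function(x) x@groupIds)

#' @rdname GraphDataset-class
#' @export
setMethod("manifest", "GraphDataset", function(x) x@manifest)

#' @rdname GraphDataset-class
#' @export
setMethod("length", "GraphDataset", function(x) length(x@graphs))

#' @rdname GraphDataset-class
#' @param i index.
#' @export
setMethod("[[", "GraphDataset", function(x, i) x@graphs[[i]])

#' @rdname GraphDataset-class
#' @export
setMethod("show", "GraphDataset", function(object) {
  cat("GraphDataset:", length(object@graphs), "graphs,",
      length(unique(object@groupIds)), "tautomer groups;",
      sum(object@labels == 1L), "positive /", sum(object@labels == 0L),
      "negative\n")
  if (!is.null(object@manifest$n_before)) {
    cat("  augmentation:", object@manifest$n_before, "->",
        object@manifest$n_after, "examples\n")
  }
})

#' @rdname GatModel-class
#' @param object a \linkS4class{GatModel}.
#' @export
setMethod("show", "GatModel", function(object) {
  cfg <- object@config
  cat("GatModel:", cfg$n_gat_layers, "GAT layer(s), hidden", cfg$hidden_dim,
      ",", cfg$n_attention_heads, "attention heads\n")
  cat("  ", if (object@trained) "trained" else "untrained",
      "; input feature set", object@featureMeta$feature_version %||% "?", "\n")
})

#' @rdname EvalReport-class
#' @export
setMethod("perRepeat", "EvalReport", function(x) x@perRepeat)

#' @rdname EvalReport-class
#' @export
setMethod("meanAccuracy", "EvalReport", function(x) x@meanAccuracy)

#' @rdname EvalReport-class
#' @export
setMethod("show", "EvalReport", function(object) {
  cat("EvalReport over", object@nRepeats, "repeat(s): mean test accuracy",
      sprintf("%.3f", object@meanAccuracy),
      sprintf("(sd %.3f)", object@sdAccuracy), "\n")
})

#' @rdname AttributionMap-class
#' @param object an \linkS4class{AttributionMap}.
#' @export
setMethod("show", "AttributionMap", function(object) {
  cat("AttributionMap:", object@smiles, "\n")
  cat("  prediction:", sprintf("%.3f", object@prediction), ";",
      length(object@atomWeights), "atom weights;",
      length(object@substructureValues), "substructure value(s)\n")
})

#' @rdname AOIProfile-class
#' @param object an \linkS4class{AOIProfile}.
#' @export
setMethod("show", "AOIProfile", function(object) {
  cat(sprintf("AOIProfile: %s x %s at %g mg/L\n",
              object@strain, object@compound, object@dose))
  cat(sprintf("  endpoint AOI %.1f%% (max %.1f%%), p = %.3g%s\n",
              object@summaryEnd, object@summaryMax, object@pValue,
              if (isTRUE(object@significant)) " *" else ""))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
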