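#' @import methods
NULL

#' MoleculeGraph: graph representation of one molecule
#'
#' Container for the featurized molecular graph consumed by the
#' graph-attention classifier. Nodes are heavy atoms with a fixed-layout
#' feature vector (element one-hot over ten common elements plus "other",
#' heavy-atom degree one-hot, formal charge, aromaticity flag, attached
#' hydrogen count); edges are directed bond arcs, present in both directions,
#' with bond-order one-hot, ring and conjugation flags. The feature layout is
#' versioned in \code{metadata()} so trained models can refuse incompatible
#' inputs.
#'
#' @slot smiles canonical SMILES the graph was built from.
#' @slot nodeFeatures numeric matrix, one row per atom.
#' @slot edgeList integer matrix with columns \code{from}, \code{to};
#'   symmetric (both arc directions present).
#' @slot edgeFeatures numeric matrix, one row per directed arc.
#' @slot atomMap integer vector mapping node index to atom index of the
#'   canonicalized molfile.
#' @slot metadata list; includes \code{feature_version}, feature column
#'   names, and the aromatic/ring annotation used.
#' @exportClass MoleculeGraph
setClass("MoleculeGraph", representation(
  smiles = "character",
  nodeFeatures = "matrix",
  edgeList = "matrix",
  edgeFeatures = "matrix",
  atomMap = "integer",
  metadata = "list"
))

setValidity("MoleculeGraph", function(object) {
  n <- nrow(object@nodeFeatures)
  e <- object@edgeList
  msgs <- character(0)
  if (n < 1) msgs <- c(msgs, "node count must be >= 1")
  if (nrow(e) > 0) {
    if (any(e < 1) || any(e > n)) msgs <- c(msgs, "edge indices out of range")
    key <- paste(e[, 1], e[, 2])
    rev <- paste(e[, 2], e[, 1])
    if (!all(rev %in% key)) msgs <- c(msgs, "edge list must be symmetric")
    if (nrow(object@edgeFeatures) != nrow(e)) {
      msgs <- c(msgs, "edgeFeatures rows must match edgeList rows")
    }
  }
  if (length(object@atomMap) != n) msgs <- c(msgs, "atomMap length must equal node count")
  if (length(msgs)) msgs else TRUE
})

#' TautomerGroup: a parent compound and its enumerated tautomers
#'
#' The unit of split assignment for leakage-free dataset construction: all
#' tautomeric spellings of one compound share its identity and label, and a
#' split assigns the whole group to a single partition.
#'
#' @slot parentId compound identifier.
#' @slot members canonical SMILES of all tautomeric forms, parent first,
#'   unique.
#' @slot label integer activity label (0/1, or NA when unset) shared by all
#'   members.
#' @exportClass TautomerGroup
setClass("TautomerGroup", representation(
  parentId = "character",
  members = "character",
  label = "integer"
))

setValidity("TautomerGroup", function(object) {
  msgs <- character(0)
  if (length(object@members) < 1) msgs <- c(msgs, "members must be non-empty")
  if (anyDuplicated(object@members)) msgs <- c(msgs, "members must be unique")
  if (!is.na(object@label) && !object@label %in% c(0L, 1L)) {
    msgs <- c(msgs, "label must be 0, 1 or NA")
  }
  if (length(msgs)) msgs else TRUE
})

#' SplitPlan: repeated group-level train/validation/test assignments
#'
#' @slot fractions named numeric of length 3 (train, validation, test),
#'   summing to 1.
#' @slot nRepeats number of independent random splits.
#' @slot seed integer seed the plan was drawn under.
#' @slot assignments list of length \code{nRepeats}; each element a named
#'   character vector mapping group id to \code{"train"}, \code{"validation"}
#'   or \code{"test"}.
#' @exportClass SplitPlan
setClass("SplitPlan", representation(
  fractions = "numeric",
  nRepeats = "integer",
  seed = "integer",
  assignments = "list"
))

setValidity("SplitPlan", function(object) {
  msgs <- character(0)
  if (length(object@fractions) != 3 || abs(sum(object@fractions) - 1) > 1e-8) {
    msgs <- c(msgs, "fractions must be length 3 and sum to 1")
  }
  if (length(object@assignments) != object@nRepeats) {
    msgs <- c(msgs, "assignments length must equal nRepeats")
  }
  for (a in object@assignments) {
    if (!all(a %in% c("train", "validation", "test"))) {
      msgs <- c(msgs, "assignments must map to train/validation/test")
      break
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' GraphDataset: labeled molecular graphs with group index
#'
#' The assembled modeling dataset: one \linkS4class{MoleculeGraph} per SMILES
#' example, its inherited binary label, the tautomer-group id used as the
#' leakage key, and a manifest recording augmentation bookkeeping (counts
#' before/after augmentation per class, cross-parent collisions).
#'
#' @slot graphs list of \linkS4class{MoleculeGraph}.
#' @slot smiles canonical SMILES per example.
#' @slot labels integer 0/1 per example.
#' @slot groupIds character group (parent compound) id per example.
#' @slot manifest list of augmentation bookkeeping.
#' @exportClass GraphDataset
setClass("GraphDataset", representation(
  graphs = "list",
  smiles = "character",
  labels = "integer",
  groupIds = "character",
  manifest = "list"
))

setValidity("GraphDataset", function(object) {
  n <- length(object@graphs)
  if (length(object@labels) != n || length(object@groupIds) != n ||
      length(object@smiles) != n) {
    return("graphs, smiles, labels and groupIds must have equal length")
  }
  TRUE
})

#' GatModel: graph-attention network classifier
#'
#' Holds the architecture configuration, the parameter tensors, and the
#' feature-layout metadata the model was built against. Message passing is a
#' stack of graph-attention (GAT) convolution layers; node embeddings then
#' pass through one multi-head self-attention layer, are pooled by
#' concatenated global max and global mean pooling, and classified by two
#' fully connected layers ending in a single logit.
#'
#' @slot config list of hyperparameters (see \code{\link{gatConfig}}).
#' @slot params named list of parameter matrices/vectors.
#' @slot featureMeta list describing the expected input feature layout.
#' @slot trained logical.
#' @slot history data.frame of per-epoch training/validation loss and
#'   accuracy (empty until trained).
#' @exportClass GatModel
setClass("GatModel", representation(
  config = "list",
  params = "list",
  featureMeta = "list",
  trained = "logical",
  history = "data.frame"
))

#' EvalReport: repeat-averaged classification performance
#'
#' @slot perRepeat data.frame with one row per split repeat: accuracy,
#'   sensitivity, specificity and confusion counts on the test partition.
#' @slot meanAccuracy arithmetic mean of per-repeat test accuracies.
#' @slot sdAccuracy standard deviation across repeats.
#' @slot nRepeats number of repeats.
#' @exportClass EvalReport
setClass("EvalReport", representation(
  perRepeat = "data.frame",
  meanAccuracy = "numeric",
  sdAccuracy = "numeric",
  nRepeats = "integer"
))

setValidity("EvalReport", function(object) {
  msgs <- character(0)
  if (nrow(object@perRepeat) != object@nRepeats) {
    msgs <- c(msgs, "perRepeat rows must equal nRepeats")
  }
  acc <- object@perRepeat$accuracy
  if (any(acc < 0 | acc > 1)) msgs <- c(msgs, "accuracies must lie in [0, 1]")
  if (abs(object@meanAccuracy - mean(acc)) > 1e-8) {
    msgs <- c(msgs, "meanAccuracy must equal the mean of per-repeat accuracies")
  }
  if (length(msgs)) msgs else TRUE
})

#' AttributionMap: per-molecule explanation of a prediction
#'
#' @slot smiles canonical SMILES.
#' @slot atomWeights nonnegative per-atom attention saliency, summing to 1.
#' @slot substructureValues named numeric of Shapley values per matched
#'   substructure pattern (signed).
#' @slot prediction predicted probability of activity.
#' @exportClass AttributionMap
setClass("AttributionMap", representation(
  smiles = "character",
  atomWeights = "numeric",
  substructureValues = "numeric",
  prediction = "numeric"
))

setValidity("AttributionMap", function(object) {
  msgs <- character(0)
  if (any(object@atomWeights < 0)) msgs <- c(msgs, "atom weights must be nonnegative")
  if (abs(sum(object@atomWeights) - 1) > 1e-6) {
    msgs <- c(msgs, "atom weights must sum to 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' AOIProfile: inhibition profile for one strain x compound x dose
#'
#' Per-timepoint ammonia oxidation inhibition percentages (defined only after
#' the inhibitor addition time), endpoint and maximum summaries, propagated
#' replicate uncertainty, and the significance of the endpoint comparison
#' against the solvent control.
#'
#' @slot strain strain identifier.
#' @slot compound compound identifier (treatment).
#' @slot dose applied dose in mg/L.
#' @slot table data.frame with columns \code{time_h}, \code{aoi},
#'   \code{aoi_sd}, \code{p_value}, \code{defined}.
#' @slot summaryEnd AOI\% at the final defined timepoint.
#' @slot summaryMax maximum AOI\% over defined post-addition timepoints.
#' @slot replicateSd propagated replicate standard deviation at the endpoint.
#' @slot significant logical flag for the endpoint test.
#' @slot pValue endpoint p-value versus control.
#' @exportClass AOIProfile
setClass("AOIProfile", representation(
  strain = "character",
  compound = "character",
  dose = "numeric",
  table = "data.frame",
  summaryEnd = "numeric",
  summaryMax = "numeric",
  replicateSd = "numeric",
  significant = "logical",
  pValue = "numeric"
))
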