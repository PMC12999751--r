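# Molecule -> graph featurization for the classifier.
#
# Node feature layout (version "bni-feat-1"):
#   [1:11]  element one-hot: C N O S P F Cl Br I B other
#   [12:15] heavy-atom degree one-hot: 1, 2, 3, >=4
#   [16]    formal charge (integer, signed)
#   [17]    aromatic flag
#   [18]    attached hydrogen count
# Edge feature layout (per directed arc):
#   [1:3]   kekulized bond order one-hot: single, double, triple
#   [4]     ring membership flag
#   [5]     conjugation flag (aromatic, or both endpoints carry a multiple bond)

FEATURE_VERSION <- "bni-feat-1"
FEATURE_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B")

node_feature_names <- function() {
  c(paste0("elem_", c(FEATURE_ELEMENTS, "other")),
    paste0("deg_", c("1", "2", "3", "4plus")),
    "charge", "aromatic", "h_count")
}

edge_feature_names <- function() {
  c("order_single", "order_double", "order_triple", "in_ring", "conjugated")
}

#' Featurize a molecule for the graph-attention classifier
#'
#' Parses (and canonicalizes) a SMILES string and returns its
#' \linkS4class{MoleculeGraph}: per-atom feature vectors, a symmetric directed
#' edge list over the heavy-atom skeleton, and per-arc bond features. Unknown
#' elements map to the "other" element slot rather than failing. The layout is
#' fixed and versioned so featurization of a canonical SMILES is reproducible
#' bit for bit.
#'
#' @param smiles a single SMILES string.
#' @return a \linkS4class{MoleculeGraph}.
#' @examples
#' g <- featurizeSmiles("CCO")
#' nrow(nodeFeatures(g))  # 3 heavy atoms
#' @export
featurizeSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  g <- parse_molgraph(smiles)
  molgraph_to_molecule_graph(g)
}

molgraph_to_molecule_graph <- function(g) {
  n <- length(g$element)
  nf <- matrix(0, nrow = n, ncol = 18,
               dimnames = list(NULL, node_feature_names()))
  ei <- match(g$element, FEATURE_ELEMENTS)
  ei[is.na(ei)] <- 11L
  nf[cbind(seq_len(n), ei)] <- 1

  deg <- integer(n)
  if (nrow(g$bonds) > 0) {
    tab <- table(factor(c(g$bonds[, "i"], g$bonds[, "j"]), levels = seq_len(n)))
    deg <- as.integer(tab)
  }
  dslot <- pmin(pmax(deg, 1L), 4L)            # degree-0 (single atom) -> slot 1
  nf[cbind(seq_len(n), 11L + dslot)] <- 1
  nf[, "charge"] <- g$charge
  nf[, "aromatic"] <- as.numeric(g$aromatic)
  nf[, "h_count"] <- g$hcount

  nb <- nrow(g$bonds)
  if (nb > 0) {
    has_multiple <- logical(n)
    mult <- g$bonds[, "order"] >= 2
    has_multiple[g$bonds[mult, "i"]] <- TRUE
    has_multiple[g$bonds[mult, "j"]] <- TRUE
    arom_bond <- g$aromatic[g$bonds[, "i"]] & g$aromatic[g$bonds[, "j"]] & g$ring_bond
    conj <- arom_bond | (has_multiple[g$bonds[, "i"]] & has_multiple[g$bonds[, "j"]])
    ef1 <- matrix(0, nrow = nb, ncol = 5, dimnames = list(NULL, edge_feature_names()))
    ef1[cbind(seq_len(nb), pmin(g$bonds[, "order"], 3L))] <- 1
    ef1[, "in_ring"] <- as.numeric(g$ring_bond)
    ef1[, "conjugated"] <- as.numeric(conj)
    el <- rbind(
      cbind(from = g$bonds[, "i"], to = g$bonds[, "j"]),
      cbind(from = g$bonds[, "j"], to = g$bonds[, "i"])
    )
    ef <- rbind(ef1, ef1)
  } else {
    el <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("from", "to")))
    ef <- matrix(numeric(0), ncol = 5, dimnames = list(NULL, edge_feature_names()))
  }
  storage.mode(el) <- "integer"

  new("MoleculeGraph",
      smiles = g$smiles,
      nodeFeatures = nf,
      edgeList = el,
      edgeFeatures = ef,
      atomMap = seq_len(n),
      metadata = list(
        feature_version = FEATURE_VERSION,
        node_features = node_feature_names(),
        edge_features = edge_feature_names(),
        elements = g$element
      ))
}
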