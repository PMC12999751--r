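# Substructure patterns and matching.
#
# A pattern is a small labelled graph: atoms constrained by element (one or
# several alternatives), aromaticity (NA = don't care) and a minimum attached
# hydrogen count; bonds constrained by order (NA = any) and aromaticity.
# Matching runs the LAD non-induced subgraph isomorphism solver of igraph with
# per-atom compatibility domains, followed by bond-order filtering. Matched
# instances are deduplicated by their atom set.

#' Define a substructure pattern
#'
#' @param name pattern name used in reports.
#' @param atoms data.frame with columns \code{element} (character; "*" for
#'   any), optional \code{aromatic} (logical or NA) and \code{min_h}
#'   (minimum attached hydrogens, default 0).
#' @param bonds data.frame with columns \code{i}, \code{j} and optional
#'   \code{order} (1/2/3 or NA for any) and \code{aromatic}; may be empty for
#'   single-atom patterns.
#' @return an object of class \code{bni_pattern}.
#' @examples
#' # carbonyl C=O
#' substructurePattern("carbonyl",
#'   atoms = data.frame(element = c("C", "O")),
#'   bonds = data.frame(i = 1, j = 2, order = 2))
#' @export
substructurePattern <- function(name, atoms, bonds = NULL) {
  stopifnot(is.character(name), nrow(atoms) >= 1)
  if (is.null(atoms$aromatic)) atoms$aromatic <- NA
  if (is.null(atoms$min_h)) atoms$min_h <- 0L
  if (is.null(bonds) || nrow(bonds) == 0) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0),
                        aromatic = logical(0))
  } else {
    if (is.null(bonds$order)) bonds$order <- NA_integer_
    if (is.null(bonds$aromatic)) bonds$aromatic <- NA
  }
  structure(list(name = name, atoms = atoms, bonds = bonds),
            class = "bni_pattern")
}

#' @export
print.bni_pattern <- function(x, ...) {
  cat("substructure pattern", sQuote(x$name), "-", nrow(x$atoms), "atom(s),",
      nrow(x$bonds), "bond(s)\n")
  invisible(x)
}

#' Default structural-alert pattern vocabulary
#'
#' A set of substructure patterns used for Shapley attribution and structural
#' alert reporting. It covers motifs repeatedly flagged for nitrification
#' inhibitors — beta-hydroxy acid, aryl amine (C-NH-c), aryl ether (c-O-C),
#' aryl hydroxyl (c-OH), ortho acyl phenol chain (O-c-c-C=O) — together with
#' common decorations (hydroxyl, carboxyl, ketone, ester, methoxy, primary
#' amine) and the thiourea/thiocarbonyl motifs used as the planted
#' pharmacophore in the synthetic benchmark.
#'
#' @return named list of \code{bni_pattern} objects.
#' @export
alertPatterns <- function() {
  p <- list(
    hydroxyl = substructurePattern("hydroxyl",
      atoms = data.frame(element = "O", min_h = 1L)),
    carboxyl = substructurePattern("carboxyl",
      atoms = data.frame(element = c("C", "O", "O"), min_h = c(0L, 0L, 1L)),
      bonds = data.frame(i = c(1, 1), j = c(2, 3), order = c(2, 1))),
    beta_hydroxy_acid = substructurePattern("beta_hydroxy_acid",
      atoms = data.frame(element = c("O", "C", "O", "C", "C", "O"),
                         min_h = c(0L, 0L, 1L, 0L, 0L, 1L)),
      bonds = data.frame(i = c(1, 2, 2, 4, 5), j = c(2, 3, 4, 5, 6),
                         order = c(2, 1, 1, 1, 1))),
    aryl_ether = substructurePattern("aryl_ether",
      atoms = data.frame(element = c("C", "O", "C"),
                         aromatic = c(TRUE, FALSE, FALSE)),
      bonds = data.frame(i = c(1, 2), j = c(2, 3), order = c(1, 1))),
    aryl_amine = substructurePattern("aryl_amine",
      atoms = data.frame(element = c("C", "N", "C"),
                         aromatic = c(FALSE, FALSE, TRUE),
                         min_h = c(0L, 1L, 0L)),
      bonds = data.frame(i = c(1, 2), j = c(2, 3), order = c(1, 1))),
    aryl_hydroxyl = substructurePattern("aryl_hydroxyl",
      atoms = data.frame(element = c("C", "O"), aromatic = c(TRUE, FALSE),
                         min_h = c(0L, 1L)),
      bonds = data.frame(i = 1, j = 2, order = 1)),
    ortho_acyl_phenol = substructurePattern("ortho_acyl_phenol",
      atoms = data.frame(element = c("O", "C", "C", "C", "O"),
                         aromatic = c(FALSE, TRUE, TRUE, FALSE, FALSE)),
      bonds = data.frame(i = c(1, 2, 3, 4), j = c(2, 3, 4, 5),
                         order = c(1, NA, 1, 2),
                         aromatic = c(NA, TRUE, NA, NA))),
    thiourea = substructurePattern("thiourea",
      atoms = data.frame(element = c("N", "C", "S", "N")),
      bonds = data.frame(i = c(1, 2, 2), j = c(2, 3, 4), order = c(1, 2, 1))),
    thiocarbonyl = substructurePattern("thiocarbonyl",
      atoms = data.frame(element = c("C", "S")),
      bonds = data.frame(i = 1, j = 2, order = 2)),
    ketone = substructurePattern("ketone",
      atoms = data.frame(element = c("C", "C", "O", "C"),
                         aromatic = c(NA, FALSE, FALSE, NA)),
      bonds = data.frame(i = c(1, 2, 2), j = c(2, 3, 4), order = c(1, 2, 1))),
    ester = substructurePattern("ester",
      atoms = data.frame(element = c("C", "O", "O", "C")),
      bonds = data.frame(i = c(1, 1, 3), j = c(2, 3, 4), order = c(2, 1, 1))),
    methoxy = substructurePattern("methoxy",
      atoms = data.frame(element = c("O", "C"), min_h = c(0L, 3L)),
      bonds = data.frame(i = 1, j = 2, order = 1)),
    primary_amine = substructurePattern("primary_amine",
      atoms = data.frame(element = "N", min_h = 2L))
  )
  p
}

# Compatibility domain of one pattern atom against a molgraph
pattern_domains <- function(pat, g) {
  n <- length(g$element)
  lapply(seq_len(nrow(pat$atoms)), function(k) {
    row <- pat$atoms[k, ]
    ok <- rep(TRUE, n)
    if (!identical(row$element, "*")) {
      ok <- ok & g$element %in% strsplit(row$element, "|", fixed = TRUE)[[1]]
    }
    if (!is.na(row$aromatic)) ok <- ok & (g$aromatic == row$aromatic)
    if (row$min_h > 0) ok <- ok & (g$hcount >= row$min_h)
    which(ok)
  })
}

#' Match a substructure pattern against a molecule
#'
#' Finds all instances of a pattern in a molecule, returning the matched atom
#' index sets (deduplicated: two matches covering the same atoms count once).
#' Atom indices refer to the heavy atoms of the canonicalized molecule, the
#' same indexing used by \code{\link{featurizeSmiles}} and atom-level
#' attribution.
#'
#' @param smiles SMILES string (or a \linkS4class{MoleculeGraph}).
#' @param pattern a \code{bni_pattern} from \code{\link{substructurePattern}}.
#' @return list of integer vectors (one per instance); empty list if no match.
#' @examples
#' length(matchSubstructure("CC(C)=O", alertPatterns()$hydroxyl))  # 0
#' @export
matchSubstructure <- function(smiles, pattern) {
  g <- if (is(smiles, "MoleculeGraph")) parse_molgraph(smiles@smiles)
       else parse_molgraph(smiles)
  doms <- pattern_domains(pattern, g)
  if (any(lengths(doms) == 0)) return(list())
  np <- nrow(pattern$atoms)

  if (np == 1L) {
    return(lapply(doms[[1]], function(i) i))
  }
  if (nrow(g$bonds) == 0) return(list())

  gt <- igraph::graph_from_edgelist(g$bonds[, c("i", "j"), drop = FALSE],
                                    directed = FALSE)
  gt <- igraph::add_vertices(gt, max(0, length(g$element) - igraph::vcount(gt)))
  gp <- igraph::graph_from_edgelist(as.matrix(pattern$bonds[, c("i", "j")]),
                                    directed = FALSE)
  if (igraph::vcount(gp) < np) gp <- igraph::add_vertices(gp, np - igraph::vcount(gp))

  maps <- tryCatch(
    igraph::subgraph_isomorphisms(pattern = gp, target = gt, method = "lad",
                                  induced = FALSE, domains = doms),
    error = function(e) list()
  )
  if (length(maps) == 0) return(list())

  ok_bond <- function(map) {
    for (r in seq_len(nrow(pattern$bonds))) {
      ti <- map[pattern$bonds$i[r]]; tj <- map[pattern$bonds$j[r]]
      bi <- bond_index(g, ti, tj)
      if (length(bi) != 1) return(FALSE)
      want <- pattern$bonds$order[r]
      if (!is.na(want) && g$bonds[bi, "order"] != want) {
        # kekulized aromatic bonds may carry either order; accept when the
        # pattern bond is explicitly aromatic
        if (!isTRUE(pattern$bonds$aromatic[r])) return(FALSE)
      }
      arom_b <- g$ring_bond[bi] && g$aromatic[ti] && g$aromatic[tj]
      want_ar <- pattern$bonds$aromatic[r]
      if (!is.na(want_ar) && arom_b != want_ar) return(FALSE)
    }
    TRUE
  }

  inst <- list()
  seen <- character(0)
  for (m in maps) {
    map <- as.integer(m)
    if (!ok_bond(map)) next
    key <- paste(sort(map), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    inst[[length(inst) + 1L]] <- map
  }
  inst
}
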