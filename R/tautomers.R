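# Tautomer enumeration under nine named transformation classes, used to
# augment training data for the activity classifier.
#
# Eight of the nine classes are 1,3 proton shifts: a donor atom D carrying at
# least one hydrogen, single-bonded to a center atom C that is double-bonded
# to an acceptor atom A, rewrites as D=C-A with the hydrogen moving to A.
# The rewrite itself only flips the two bond orders on the kekulized
# heavy-atom graph; hydrogen movement is implied by valence when the product
# is re-perceived by the chemistry toolkit. Each class specializes the engine
# by element, ring and aromaticity constraints on (D, C, A). The nitro class
# additionally includes protonation/deprotonation rewrites that change the
# hydrogen count and net charge; products keep the parent's group membership
# and label regardless.
#
# Rule-set version: changing any pattern below must bump TAUTOMER_RULES_VERSION,
# since augmentation counts are reproducible only for a fixed rule set.

TAUTOMER_RULES_VERSION <- "bni-taut-1"

# One direction of a 1,3 shift: element sets for donor/center/acceptor plus
# optional constraints. `d_arom`/`a_ring` etc. are NA (don't care) or logical.
shift_spec <- function(d, c, a, d_arom = NA, c_ring = NA, a_ring = NA,
                       dc_ring = NA, ca_ring = NA, extra = NULL) {
  list(d = d, c = c, a = a, d_arom = d_arom, c_ring = c_ring, a_ring = a_ring,
       dc_ring = dc_ring, ca_ring = ca_ring, extra = extra)
}

#' Tautomer transformation rule set
#'
#' Returns the versioned rule set implementing the nine tautomeric
#' transformation classes used for dataset augmentation: keto-enol,
#' imine-enamine, amide-imidic acid, lactam-lactim, pyridine-pyridol,
#' heteroatom proton transfer, protonation/deprotonation of nitro groups,
#' thione-thiol and azole tautomerism. Each class is an explicit
#' substructure-rewrite rule on the kekulized molecular graph; most are
#' element-constrained 1,3 proton shifts. Subset by name to restrict
#' enumeration to particular classes.
#'
#' @param classes character vector of class names to keep (default: all nine).
#' @return named list of rules, with attribute \code{version}.
#' @examples
#' names(tautomerRules())
#' tautomerRules("keto_enol")
#' @export
tautomerRules <- function(classes = NULL) {
  non_arom <- function(g, d, c, a) !g$aromatic[c]
  rules <- list(
    keto_enol = list(shifts = list(
      # keto -> enol: H-C-C=O  =>  C=C-O-H
      shift_spec("C", "C", "O", extra = non_arom),
      # enol -> keto
      shift_spec("O", "C", "C", extra = function(g, d, c, a) {
        !g$aromatic[c] && !g$aromatic[a]
      })
    )),
    imine_enamine = list(shifts = list(
      # imine -> enamine: H-C-C=N  =>  C=C-N-H
      shift_spec("C", "C", "N", extra = non_arom),
      # enamine -> imine
      shift_spec("N", "C", "C", extra = function(g, d, c, a) {
        !g$aromatic[c] && !g$aromatic[a]
      })
    )),
    amide_imidic = list(shifts = list(
      # amide -> imidic acid: H-N-C=O  =>  N=C-O-H  (acyclic amide bond)
      shift_spec("N", "C", "O", dc_ring = FALSE, extra = non_arom),
      shift_spec("O", "C", "N", ca_ring = FALSE, extra = non_arom)
    )),
    lactam_lactim = list(shifts = list(
      # same shift restricted to ring amides
      shift_spec("N", "C", "O", dc_ring = TRUE, extra = non_arom),
      shift_spec("O", "C", "N", ca_ring = TRUE, extra = non_arom)
    )),
    pyridine_pyridol = list(shifts = list(
      # 2-hydroxy azine -> 2-one: H-O-c(ring)=N(ring)  =>  O=C-N-H
      shift_spec("O", "C", "N", c_ring = TRUE, a_ring = TRUE, ca_ring = TRUE,
                 extra = function(g, d, c, a) g$aromatic[c] && !g$ring_atom[d]),
      # 2-one -> 2-hydroxy azine
      shift_spec("N", "C", "O", c_ring = TRUE, dc_ring = TRUE,
                 extra = function(g, d, c, a) g$ring_atom[d] && !g$ring_atom[a])
    )),
    heteroatom_proton_transfer = list(shifts = list(
      # generic 1,3 shift between heteroatoms through any center
      shift_spec(c("N", "O", "S"), c("C", "N"), c("N", "O", "S"))
    )),
    nitro = list(nitro = TRUE),
    thione_thiol = list(shifts = list(
      # thione -> thiol: H-X-C=S  =>  X=C-S-H  (X = C or N)
      shift_spec(c("C", "N"), "C", "S", extra = non_arom),
      shift_spec("S", "C", c("C", "N"), extra = function(g, d, c, a) {
        !g$aromatic[c] && !g$aromatic[a]
      })
    )),
    azole = list(shifts = list(
      # annular N-H shift in azoles: H-N(ring)-C(ring)=N(ring)
      shift_spec("N", "C", "N", c_ring = TRUE, a_ring = TRUE,
                 dc_ring = TRUE, ca_ring = TRUE,
                 extra = function(g, d, c, a) g$ring_atom[d])
    ))
  )
  if (!is.null(classes)) {
    missing <- setdiff(classes, names(rules))
    if (length(missing) > 0) {
      stop("unknown tautomer rule class(es): ", paste(missing, collapse = ", "))
    }
    rules <- rules[classes]
  }
  attr(rules, "version") <- TAUTOMER_RULES_VERSION
  rules
}

# All products of the 1,3-shift specs of one rule applied to molgraph g.
apply_shift_rule <- function(g, rule) {
  out <- character(0)
  if (is.null(rule$shifts) || nrow(g$bonds) == 0) return(out)
  nbr <- molgraph_neighbors(g)
  singles <- which(g$bonds[, "order"] == 1L)
  doubles <- which(g$bonds[, "order"] == 2L)
  if (length(singles) == 0 || length(doubles) == 0) return(out)
  for (spec in rule$shifts) {
    for (sb in singles) {
      for (dir in 1:2) {
        d <- g$bonds[sb, if (dir == 1) "i" else "j"]
        cc <- g$bonds[sb, if (dir == 1) "j" else "i"]
        if (g$hcount[d] < 1) next
        if (!g$element[d] %in% spec$d) next
        if (!g$element[cc] %in% spec$c) next
        if (!is.na(spec$d_arom) && g$aromatic[d] != spec$d_arom) next
        if (!is.na(spec$c_ring) && g$ring_atom[cc] != spec$c_ring) next
        if (!is.na(spec$dc_ring) && g$ring_bond[sb] != spec$dc_ring) next
        for (db in doubles) {
          a <- NA_integer_
          if (g$bonds[db, "i"] == cc) a <- g$bonds[db, "j"]
          else if (g$bonds[db, "j"] == cc) a <- g$bonds[db, "i"]
          if (is.na(a) || a == d) next
          if (!g$element[a] %in% spec$a) next
          if (!is.na(spec$a_ring) && g$ring_atom[a] != spec$a_ring) next
          if (!is.na(spec$ca_ring) && g$ring_bond[db] != spec$ca_ring) next
          if (!is.null(spec$extra) && !isTRUE(spec$extra(g, d, cc, a))) next
          h <- g
          h$bonds[sb, "order"] <- 2L
          h$bonds[db, "order"] <- 1L
          h$hcount[d] <- h$hcount[d] - 1L
          h$hcount[a] <- h$hcount[a] + 1L
          h$smiles <- NA_character_
          can <- molgraph_to_canonical(h)
          if (!is.na(can)) out <- c(out, can)
        }
      }
    }
  }
  out
}

# Nitro-group rewrites: aci-nitro 1,3 shift plus O protonation/deprotonation.
apply_nitro_rule <- function(g) {
  out <- character(0)
  if (nrow(g$bonds) == 0) return(out)
  nplus <- which(g$element == "N" & g$charge == 1L)
  for (nn in nplus) {
    rows <- which(g$bonds[, "i"] == nn | g$bonds[, "j"] == nn)
    other <- ifelse(g$bonds[rows, "i"] == nn, g$bonds[rows, "j"], g$bonds[rows, "i"])
    ominus <- other[g$element[other] == "O" & g$charge[other] == -1L &
                      g$bonds[rows, "order"] == 1L]
    odbl <- other[g$element[other] == "O" & g$bonds[rows, "order"] == 2L]
    if (length(odbl) == 0) next
    # aci-nitro shift: alpha C-H moves to the doubly bonded O
    if (length(ominus) > 0) {
      alpha <- other[g$element[other] == "C" & g$bonds[rows, "order"] == 1L]
      for (ca in alpha) {
        if (g$hcount[ca] < 1 || g$aromatic[ca]) next
        h <- g
        h$bonds[bond_index(g, ca, nn), "order"] <- 2L
        h$bonds[bond_index(g, nn, odbl[1]), "order"] <- 1L
        h$hcount[ca] <- h$hcount[ca] - 1L
        h$smiles <- NA_character_
        can <- molgraph_to_canonical(h)
        if (!is.na(can)) out <- c(out, can)
      }
    }
    # protonation of the O-: neutral OH (changes H count and net charge)
    for (om in ominus) {
      h <- g
      h$charge[om] <- 0L
      h$hcount[om] <- h$hcount[om] + 1L
      h$smiles <- NA_character_
      can <- molgraph_to_canonical(h)
      if (!is.na(can)) out <- c(out, can)
    }
    # deprotonation of a nitro O-H back to O-
    oh <- other[g$element[other] == "O" & g$charge[other] == 0L &
                  g$bonds[rows, "order"] == 1L]
    for (om in oh) {
      if (g$hcount[om] < 1) next
      h <- g
      h$charge[om] <- -1L
      h$hcount[om] <- h$hcount[om] - 1L
      h$smiles <- NA_character_
      can <- molgraph_to_canonical(h)
      if (!is.na(can)) out <- c(out, can)
    }
  }
  out
}

#' Enumerate tautomers of a compound
#'
#' Applies the tautomeric transformation classes of \code{\link{tautomerRules}}
#' to a molecule as one-step graph rewrites (optionally iterated to a k-step
#' closure), deduplicates products by canonical SMILES, and returns a
#' \linkS4class{TautomerGroup} whose first member is always the canonicalized
#' input. Products that the chemistry toolkit cannot sanitize are dropped with
#' a message rather than failing. Enumeration is deterministic: members beyond
#' the parent are ordered canonically (lexicographic) and truncated at
#' \code{cap}.
#'
#' Heavy-atom composition is conserved by every rule; hydrogen count is
#' conserved by every class except nitro protonation/deprotonation, whose
#' products nevertheless stay in the parent's group with the parent's label.
#'
#' @param smiles a single SMILES string (the parent compound).
#' @param rules rule set from \code{\link{tautomerRules}}.
#' @param cap maximum number of group members (including the parent).
#' @param steps number of rewrite passes (1 = single-step enumeration).
#' @param parentId identifier recorded for the group (default: the canonical
#'   parent SMILES).
#' @param label optional binary activity label shared by the group.
#' @return a \linkS4class{TautomerGroup}.
#' @examples
#' members(enumerateTautomers("CC(C)=O"))   # acetone + propen-2-ol
#' @export
enumerateTautomers <- function(smiles, rules = tautomerRules(), cap = 32L,
                               steps = 1L, parentId = NULL, label = NA_integer_) {
  stopifnot(length(smiles) == 1L, cap >= 1L, steps >= 1L)
  parent <- canonicalizeSmiles(smiles)
  seen <- parent
  frontier <- parent
  for (step in seq_len(steps)) {
    products <- character(0)
    for (s in frontier) {
      g <- parse_molgraph(s)
      for (rn in names(rules)) {
        rule <- rules[[rn]]
        prods <- if (isTRUE(rule$nitro)) apply_nitro_rule(g) else apply_shift_rule(g, rule)
        products <- c(products, prods)
      }
    }
    frontier <- setdiff(unique(products), seen)
    seen <- c(seen, frontier)
    if (length(frontier) == 0) break
  }
  others <- sort(setdiff(seen, parent))
  members <- c(parent, others)
  if (length(members) > cap) members <- members[seq_len(cap)]
  new("TautomerGroup",
      parentId = if (is.null(parentId)) parent else as.character(parentId),
      members = members,
      label = as.integer(label))
}
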