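# Synthetic structure-activity libraries with a planted pharmacophore.
#
# Compounds are built by decorating ring scaffolds with substituents from a
# fixed vocabulary (hydroxyl, carboxyl, acetyl, ester/ether decorations and
# the like). A planted pharmacophore fragment (thiourea by default) is
# attached to the positive share of the library, so that before label noise
# the class label is exactly the substructure-match indicator. Positives are
# assigned EC50 = 5 mg/L and negatives EC50 = 100 mg/L, so the EC50-threshold
# labeling rule reproduces the planted label end to end.

sar_decorations <- function() {
  # fragment SMILES are parsed without re-canonicalization, so attach indices
  # refer to the written atom order
  list(
    hydroxyl = list(smiles = "O", at = 1L),
    methyl = list(smiles = "C", at = 1L),
    ethyl = list(smiles = "CC", at = 1L),
    methoxy = list(smiles = "OC", at = 1L),
    carboxyl = list(smiles = "C(=O)O", at = 1L),
    acetyl = list(smiles = "C(C)=O", at = 1L),
    acetoxy = list(smiles = "OC(C)=O", at = 1L),
    amino = list(smiles = "N", at = 1L),
    chloro = list(smiles = "Cl", at = 1L),
    amide = list(smiles = "C(N)=O", at = 1L)
  )
}

default_scaffolds <- function() {
  c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "c1ccc2ccccc2c1", "C1CCNCC1",
    "c1ccoc1")
}

#' Parameters for the structure-activity library generator
#'
#' @param n_compounds number of compounds to generate.
#' @param scaffold_library SMILES of ring scaffolds to decorate.
#' @param pharmacophore \code{bni_pattern} defining the planted activity rule
#'   (used to verify each generated molecule).
#' @param pharmacophore_fragment fragment SMILES attached to positives; its
#'   first atom is the attachment point.
#' @param label_noise probability of flipping a label, in [0, 0.5).
#' @param positive_fraction share of compounds carrying the pharmacophore.
#' @param stratified logical; exact class counts (default) versus binomial
#'   draws.
#' @param seed integer seed.
#' @return validated parameter list of class \code{sar_sim_params}.
#' @export
sarSimParams <- function(n_compounds = 300L,
                         scaffold_library = default_scaffolds(),
                         pharmacophore = alertPatterns()$thiourea,
                         pharmacophore_fragment = "NC(=S)N",
                         label_noise = 0.05,
                         positive_fraction = 0.5,
                         stratified = TRUE,
                         seed = 1L) {
  if (length(scaffold_library) < 1) stop("scaffold_library must be non-empty")
  if (label_noise < 0 || label_noise >= 0.5) {
    stop("label_noise must lie in [0, 0.5)", call. = FALSE)
  }
  if (positive_fraction < 0 || positive_fraction > 1) {
    stop("positive_fraction must lie in [0, 1]", call. = FALSE)
  }
  for (s in scaffold_library) {
    ok <- tryCatch({ parse_molgraph(s); TRUE }, error = function(e) FALSE)
    if (!ok) stop("unparseable scaffold SMILES: ", sQuote(s), call. = FALSE)
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 scaffold_library = scaffold_library,
                 pharmacophore = pharmacophore,
                 pharmacophore_fragment = pharmacophore_fragment,
                 label_noise = label_noise,
                 positive_fraction = positive_fraction,
                 stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "sar_sim_params")
}

#' Generate a synthetic structure-activity dataset
#'
#' Builds \code{n_compounds} decorated molecules. Each positive compound
#' carries the planted pharmacophore fragment; each generated molecule is
#' verified against the pharmacophore pattern so that, before label noise,
#' \code{label == 1} exactly when the pattern matches. Labels are then flipped
#' with probability \code{label_noise}, and EC50 values are assigned from the
#' final label (5 mg/L for positives, 100 mg/L for negatives). Deterministic
#' under the parameter seed.
#'
#' @param params a \code{sar_sim_params} object from \code{\link{sarSimParams}}.
#' @return data.frame with columns \code{id}, \code{name}, \code{smiles}
#'   (canonical), \code{ec50_mg_per_L}, \code{label}, and bookkeeping columns
#'   \code{planted} (pre-noise pharmacophore indicator) and \code{scaffold}.
#' @examples
#' d <- generateSarDataset(sarSimParams(n_compounds = 10, seed = 7))
#' table(d$label)
#' @export
generateSarDataset <- function(params) {
  stopifnot(inherits(params, "sar_sim_params"))
  p <- params
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(p$seed)

  decs <- sar_decorations()
  # fragments keep written atom order (no re-canonicalization of the text)
  frag_cache <- lapply(decs, function(d) parse_fragment(d$smiles))
  pharm_frag <- parse_fragment(p$pharmacophore_fragment)

  n <- p$n_compounds
  n_pos <- round(n * p$positive_fraction)
  planted <- if (p$stratified) {
    sample(c(rep(TRUE, n_pos), rep(FALSE, n - n_pos)))
  } else {
    stats::runif(n) < p$positive_fraction
  }

  rows <- vector("list", n)
  seen_smiles <- character(0)
  for (k in seq_len(n)) {
    tries <- 0L
    repeat {
      tries <- tries + 1L
      scaf_smiles <- sample(p$scaffold_library, 1)
      g <- parse_molgraph(scaf_smiles)
      open <- which(g$element == "C" & g$hcount >= 1)
      n_dec <- sample(if (planted[k]) 1:2 else 1:3, 1)
      picks <- sample(names(decs), n_dec, replace = TRUE)
      want <- n_dec + as.integer(planted[k])
      if (length(open) < want) next
      pos <- sample(open, want)
      mol <- g
      slot <- 1L
      if (planted[k]) {
        mol <- molgraph_attach(mol, pharm_frag, pos[slot], frag_at = 1L)
        slot <- slot + 1L
      }
      for (d in picks) {
        mol <- molgraph_attach(mol, frag_cache[[d]], pos[slot],
                               frag_at = decs[[d]]$at)
        slot <- slot + 1L
      }
      can <- molgraph_to_canonical(mol)
      if (is.na(can)) next
      if (can %in% seen_smiles && tries < 50L) next   # keep molecules distinct
      has_pharm <- length(matchSubstructure(can, p$pharmacophore)) > 0
      if (has_pharm != planted[k]) next   # construction must equal the rule
      seen_smiles <- c(seen_smiles, can)
      rows[[k]] <- data.frame(id = sprintf("cpd_%03d", k),
                              name = sprintf("synthetic compound %d", k),
                              smiles = can,
                              planted = planted[k],
                              scaffold = scaf_smiles,
                              stringsAsFactors = FALSE)
      break
    }
  }
  out <- do.call(rbind, rows)
  flip <- stats::runif(n) < p$label_noise
  out$label <- ifelse(xor(out$planted, flip), 1L, 0L)
  out$ec50_mg_per_L <- ifelse(out$label == 1L, 5, 100)
  out[, c("id", "name", "smiles", "ec50_mg_per_L", "label", "planted",
          "scaffold")]
}
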