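# Internal molecular graph: the kekulized heavy-atom skeleton of one molecule,
# with formal charges, implicit hydrogen counts, aromatic perception and ring
# membership. Parsing and sanitization are delegated to OpenBabel/ChemmineR;
# this structure exists so tautomer rewrites, fragment assembly, featurization
# and substructure matching all operate on one representation.
#
# Fields:
#   element  character, heavy atoms in molfile order
#   charge   integer formal charges
#   hcount   integer implicit/explicit hydrogens attached to each heavy atom
#   aromatic logical per atom (perceived aromatic ring membership)
#   bonds    matrix [i, j, order] with i < j, kekulized orders 1/2/3
#   ring_bond logical per bond row
#   smiles   canonical SMILES the graph was derived from

.molgraph_cache <- new.env(parent = emptyenv())

parse_molgraph <- function(smiles, use_cache = TRUE) {
  can <- canonicalizeSmiles(smiles)
  if (use_cache && !is.null(g <- .molgraph_cache[[can]])) return(g)
  g <- parse_smiles_text(can)
  if (use_cache) .molgraph_cache[[can]] <- g
  g
}

# Parse a SMILES string as written, WITHOUT re-canonicalization, so atom
# indices follow the written atom order. Used for substituent fragments whose
# attachment point is given as a written-order index.
parse_fragment <- function(smiles) {
  parse_smiles_text(smiles)
}

parse_smiles_text <- function(can) {
  # One explicit-H molfile carries everything: elements, kekulized bond
  # orders, charges and hydrogen counts. (A hydrogen-free single-atom molfile
  # would have no bond block, which ChemmineR's reader mishandles; the
  # explicit-H form always has bonds for organic input.)
  sdfh_txt <- ob_convert("SMI", "SDF", paste0(can, "\n"), add_h = TRUE)
  if (!nzchar(sub("[\n ]+$", "", sdfh_txt))) {
    stop("SMILES parse failure: ", sQuote(can), call. = FALSE)
  }
  sdfh <- read_sdf_text(sdfh_txt)
  abh <- ChemmineR::atomblock(sdfh)
  elh <- sub("_.*$", "", rownames(abh))
  heavy <- which(elh != "H")
  n <- length(heavy)
  if (n < 1) stop("molecule has no heavy atoms: ", sQuote(can), call. = FALSE)
  element <- elh[heavy]
  remap <- integer(length(elh))          # original index -> heavy index (0 for H)
  remap[heavy] <- seq_len(n)

  bbh <- ChemmineR::bondblock(sdfh)
  if (is.null(dim(bbh))) bbh <- matrix(bbh, ncol = 7, nrow = length(bbh) %/% 7)
  hcount <- integer(n)
  brows <- list()
  if (nrow(bbh) > 0) {
    for (r in seq_len(nrow(bbh))) {
      a <- bbh[r, 1]; b <- bbh[r, 2]; o <- bbh[r, 3]
      ha <- remap[a]; hb <- remap[b]
      if (ha > 0 && hb > 0) {
        brows[[length(brows) + 1L]] <- c(min(ha, hb), max(ha, hb), o)
      } else if (ha > 0) hcount[ha] <- hcount[ha] + 1L
      else if (hb > 0) hcount[hb] <- hcount[hb] + 1L
    }
  }
  bonds <- if (length(brows) > 0) do.call(rbind, brows) else matrix(integer(0), ncol = 3)
  storage.mode(bonds) <- "integer"
  colnames(bonds) <- c("i", "j", "order")

  charge <- integer(n)
  chg <- parse_mchg(sdfh_txt)
  if (nrow(chg) > 0) {
    for (r in seq_len(nrow(chg))) {
      h <- remap[chg[r, 1]]
      if (h > 0) charge[h] <- chg[r, 2]
    }
  }

  ar <- perceive_rings(sdfh, element, bonds, remap)

  g <- structure(list(
    element = element, charge = charge, hcount = hcount,
    aromatic = ar$atom_aromatic, bonds = bonds, ring_bond = ar$ring_bond,
    ring_atom = ar$ring_atom, smiles = can
  ), class = "bni_molgraph")
  g
}

read_sdf_text <- function(txt) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(txt, tf)
  suppressWarnings(ChemmineR::read.SDFset(tf))[[1]]
}

# M CHG lines: "M  CHG  k  idx chg  idx chg ..."
parse_mchg <- function(sdf_txt) {
  lines <- strsplit(sdf_txt, "\n", fixed = TRUE)[[1]]
  lines <- grep("^M  CHG", lines, value = TRUE)
  out <- matrix(integer(0), ncol = 2)
  for (ln in lines) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[ ]+")[[1]])
    k <- f[1]
    pairs <- matrix(f[-1], ncol = 2, byrow = TRUE)[seq_len(k), , drop = FALSE]
    out <- rbind(out, pairs)
  }
  out
}

perceive_rings <- function(sdf, element, bonds, remap) {
  n <- length(element)
  atom_aromatic <- logical(n)
  ring_atom <- logical(n)
  ring_bond <- logical(nrow(bonds))
  if (nrow(bonds) >= 3) {
    rr <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, upper = 12, type = "all", arom = TRUE)),
      error = function(e) NULL
    )
    if (!is.null(rr) && length(rr$RINGS) > 0) {
      bond_key <- paste(bonds[, "i"], bonds[, "j"])
      for (k in seq_along(rr$RINGS)) {
        idx <- remap[as.integer(sub("^.*_", "", rr$RINGS[[k]]))]
        if (any(idx == 0)) next
        ring_atom[idx] <- TRUE
        m <- length(idx)
        pairs <- cbind(idx, idx[c(2:m, 1)])
        keys <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
        ring_bond[bond_key %in% keys] <- TRUE
        if (isTRUE(rr$AROMATIC[[k]])) atom_aromatic[idx] <- TRUE
      }
    }
  }
  list(atom_aromatic = atom_aromatic, ring_atom = ring_atom, ring_bond = ring_bond)
}

# Serialize a molgraph (possibly rewritten) back to V2000 molfile text.
# Hydrogens are left implicit: OpenBabel re-derives them from valence, which is
# exactly how the proton-shift tautomer rules realize hydrogen movement.
molgraph_to_molfile <- function(g) {
  n <- length(g$element)
  nb <- nrow(g$bonds)
  head <- c("", " BNIscreen molgraph", "",
            sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  atoms <- sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   g$element)
  bondl <- if (nb > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", g$bonds[, "i"], g$bonds[, "j"], g$bonds[, "order"])
  } else character(0)
  chg_idx <- which(g$charge != 0L)
  chgl <- character(0)
  if (length(chg_idx) > 0) {
    for (s in split(chg_idx, ceiling(seq_along(chg_idx) / 8))) {
      chgl <- c(chgl, paste0(sprintf("M  CHG%3d", length(s)),
                             paste0(sprintf("%4d%4d", s, g$charge[s]), collapse = "")))
    }
  }
  paste(c(head, atoms, bondl, chgl, "M  END", "$$$$", ""), collapse = "\n")
}

molgraph_to_canonical <- function(g) {
  molfile_to_canonical(molgraph_to_molfile(g))
}

# Heavy-atom molecular formula (hydrogens excluded), e.g. "C3 N1 O2".
heavy_formula <- function(g) {
  tab <- table(g$element)
  paste(paste0(names(tab), as.integer(tab)), collapse = " ")
}

# Neighbor list over heavy atoms
molgraph_neighbors <- function(g) {
  n <- length(g$element)
  nb <- vector("list", n)
  if (nrow(g$bonds) > 0) {
    for (r in seq_len(nrow(g$bonds))) {
      i <- g$bonds[r, "i"]; j <- g$bonds[r, "j"]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb
}

bond_index <- function(g, i, j) {
  which(g$bonds[, "i"] == min(i, j) & g$bonds[, "j"] == max(i, j))
}

# Attach `frag` to `g` by a single bond between g atom `at` and frag atom
# `frag_at` (defaults to the fragment's first atom). Used by the SAR generator.
molgraph_attach <- function(g, frag, at, frag_at = 1L) {
  off <- length(g$element)
  fb <- frag$bonds
  if (nrow(fb) > 0) fb[, c("i", "j")] <- fb[, c("i", "j")] + off
  bonds <- rbind(
    g$bonds,
    fb,
    matrix(c(min(at, frag_at + off), max(at, frag_at + off), 1L), ncol = 3)
  )
  colnames(bonds) <- c("i", "j", "order")
  structure(list(
    element = c(g$element, frag$element),
    charge = c(g$charge, frag$charge),
    hcount = c(g$hcount, frag$hcount),  # advisory; OB recomputes on write
    aromatic = c(g$aromatic, frag$aromatic),
    bonds = bonds,
    ring_bond = c(g$ring_bond, frag$ring_bond, FALSE),
    ring_atom = c(g$ring_atom, frag$ring_atom),
    smiles = NA_character_
  ), class = "bni_molgraph")
}
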