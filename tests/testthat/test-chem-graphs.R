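# SMILES canonicalization, featurization and tautomer enumeration.

test_that("canonicalization is idempotent and spelling-invariant", {
  expect_identical(canonicalizeSmiles("OCC"), canonicalizeSmiles("CCO"))
  # aromatic perception: kekulized and aromatic spellings agree
  expect_identical(canonicalizeSmiles("C1=CC=CC=C1"),
                   canonicalizeSmiles("c1ccccc1"))
  for (s in c("CCO", "c1ccccc1", "NC(=S)Nc1ccccc1", "O=C1C=CC=CN1")) {
    can <- canonicalizeSmiles(s)
    expect_identical(canonicalizeSmiles(can), can)
  }
  expect_error(canonicalizeSmiles("C1CC"), "C1CC")
})

test_that("featurization matches molecular structure", {
  g <- featurizeSmiles("CC")
  expect_equal(nrow(nodeFeatures(g)), 2)
  expect_equal(nrow(edgeList(g)), 2)   # both arc directions

  b <- featurizeSmiles("c1ccccc1")
  expect_equal(nrow(nodeFeatures(b)), 6)
  expect_equal(nrow(edgeList(b)), 12)
  expect_true(all(nodeFeatures(b)[, "aromatic"] == 1))
  expect_true(all(edgeFeatures(b)[, "in_ring"] == 1))

  e <- featurizeSmiles("CCO")
  nf <- nodeFeatures(e)
  o <- which(nf[, "elem_O"] == 1)
  expect_length(o, 1)
  expect_equal(unname(nf[o, "h_count"]), 1)

  # single heavy atom: degenerate but valid graph
  m <- featurizeSmiles("C")
  expect_equal(nrow(nodeFeatures(m)), 1)
  expect_equal(nrow(edgeList(m)), 0)
  expect_equal(unname(nodeFeatures(m)[1, "h_count"]), 4)
})

test_that("featurization of a canonical SMILES is bit-for-bit reproducible and spelling-invariant", {
  spellings <- list(c("OCC", "CCO", "C(O)C"),
                    c("c1ccccc1O", "Oc1ccccc1", "C1=CC=CC=C1O"),
                    c("NC(=S)N", "C(N)(N)=S"))
  for (sp in spellings) {
    graphs <- lapply(sp, featurizeSmiles)
    for (k in seq_along(graphs)[-1]) {
      expect_identical(nodeFeatures(graphs[[k]]), nodeFeatures(graphs[[1]]))
      expect_identical(edgeList(graphs[[k]]), edgeList(graphs[[1]]))
      expect_identical(edgeFeatures(graphs[[k]]), edgeFeatures(graphs[[1]]))
    }
  }
})

test_that("tautomer rules produce the textbook products", {
  # keto-enol: acetone -> propen-2-ol
  grp <- enumerateTautomers("CC(C)=O")
  expect_true(canonicalizeSmiles("CC(O)=C") %in% members(grp))
  expect_identical(members(grp)[1], canonicalizeSmiles("CC(C)=O"))

  # no applicable rule: methane maps to itself
  expect_identical(members(enumerateTautomers("C")), "C")

  # lactam-lactim / pyridine-pyridol: 2-hydroxypyridine <-> 2-pyridone
  grp2 <- enumerateTautomers("Oc1ccccn1")
  expect_true(canonicalizeSmiles("O=C1C=CC=CN1") %in% members(grp2))

  # thione-thiol
  grp3 <- enumerateTautomers("CC(N)=S", rules = tautomerRules("thione_thiol"))
  expect_true(canonicalizeSmiles("CC(S)=N") %in% members(grp3))

  # azole shift on an asymmetric azole
  grp4 <- enumerateTautomers("Cc1c[nH]cn1", rules = tautomerRules("azole"))
  expect_true(canonicalizeSmiles("Cc1cnc[nH]1") %in% members(grp4))
})

test_that("tautomer enumeration is deterministic and respects the cap", {
  a <- members(enumerateTautomers("NC(=S)Nc1ccccc1O"))
  b <- members(enumerateTautomers("NC(=S)Nc1ccccc1O"))
  expect_identical(a, b)
  capped <- members(enumerateTautomers("NC(=S)Nc1ccccc1O", cap = 2))
  expect_length(capped, 2)
  expect_identical(capped, a[1:2])
})

test_that("tautomer groups conserve heavy-atom formula, and hydrogens except for nitro protonation", {
  formula_of <- function(s) BNIscreen:::heavy_formula(BNIscreen:::parse_molgraph(s))
  hcount_of <- function(s) sum(BNIscreen:::parse_molgraph(s)$hcount)

  mols <- c("CC(C)=O", "CC(N)=O", "Oc1ccccn1", "CC(N)=S", "Cc1c[nH]cn1",
            "NC(=S)Nc1ccccc1", "CCC(=O)c1ccc(O)cc1")
  non_nitro <- tautomerRules(setdiff(names(tautomerRules()), "nitro"))
  for (m in mols) {
    grp <- enumerateTautomers(m, rules = non_nitro)
    ff <- vapply(members(grp), formula_of, character(1))
    hh <- vapply(members(grp), hcount_of, numeric(1))
    expect_true(all(ff == ff[1]), info = m)
    expect_true(all(hh == hh[1]), info = m)
  }

  # nitro protonation/deprotonation changes H count but not heavy atoms
  grp <- enumerateTautomers("C[N+](=O)[O-]", rules = tautomerRules("nitro"))
  ff <- vapply(members(grp), formula_of, character(1))
  expect_true(all(ff == ff[1]))
  hh <- vapply(members(grp), hcount_of, numeric(1))
  expect_true(length(unique(hh)) > 1)
})

test_that("substructure matching finds and localizes motifs", {
  pats <- alertPatterns()
  expect_length(matchSubstructure("CC(C)=O", pats$hydroxyl), 0)
  inst <- matchSubstructure("NC(=S)Nc1ccccc1", pats$thiourea)
  expect_length(inst, 1)
  g <- BNIscreen:::parse_molgraph("NC(=S)Nc1ccccc1")
  expect_setequal(g$element[inst[[1]]], c("N", "C", "S", "N"))
  # two instances of a repeated motif
  two <- matchSubstructure("OCCCO", pats$hydroxyl)
  expect_length(two, 2)
})
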