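# Attention saliency and Shapley substructure attribution.

test_that("attention weights are a normalized distribution over atoms", {
  model <- small_model()$model
  expect_equal(attentionAtomWeights(model, "C"), 1.0)   # single atom
  for (s in c("CCO", "NC(=S)Nc1ccccc1", "COc1ccc(cc1)C(=O)O")) {
    w <- attentionAtomWeights(model, s)
    expect_equal(sum(w), 1, tolerance = 1e-6)
    expect_true(all(w >= 0))
    expect_length(w, nrow(nodeFeatures(featurizeSmiles(s))))
  }
})

test_that("a single-player game gives exactly full minus baseline", {
  model <- small_model()$model
  pats <- alertPatterns()["thiourea"]
  phi <- shapleySubstructures(model, "NC(=S)NC1CCCCC1", patterns = pats)
  expect_length(phi, 1)
  expect_equal(as.numeric(phi), attr(phi, "full") - attr(phi, "baseline"),
               tolerance = 1e-10)
})

test_that("Shapley values satisfy the efficiency axiom", {
  model <- small_model()$model
  for (s in c("NC(=S)Nc1ccccc1OC", "CC(=O)Oc1ccccc1C(=O)O")) {
    phi <- suppressWarnings(shapleySubstructures(model, s))
    expect_equal(sum(phi), attr(phi, "full") - attr(phi, "baseline"),
                 tolerance = 1e-10)
  }
})

test_that("Monte-Carlo Shapley matches exact enumeration for m = 3", {
  model <- small_model()$model
  pats <- alertPatterns()[c("thiourea", "aryl_amine", "methoxy")]
  mol <- "COc1ccccc1NC(=S)N"
  exact <- shapleySubstructures(model, mol, patterns = pats)
  expect_length(exact, 3)
  expect_identical(attr(exact, "method"), "exact")
  mc <- shapleySubstructures(model, mol, patterns = pats, exact_max = 2,
                             n_samples = 2000, seed = 4)
  expect_identical(attr(mc, "method"), "monte_carlo")
  expect_lt(max(abs(as.numeric(mc) - as.numeric(exact[names(mc)]))), 0.02)
  # efficiency holds for the sampled estimate too
  expect_equal(sum(mc), attr(mc, "full") - attr(mc, "baseline"),
               tolerance = 1e-3)
  expect_error(
    shapleySubstructures(model, mol, patterns = pats, exact_max = 2,
                         n_samples = 20),
    "n_samples")
})

test_that("symmetric players receive equal values", {
  model <- small_model()$model
  # two hydroxyls in symmetric positions of a symmetric molecule
  phi <- suppressWarnings(
    shapleySubstructures(model, "OCCCCO",
                         patterns = alertPatterns()["hydroxyl"]))
  expect_length(phi, 2)
  expect_equal(phi[[1]], phi[[2]], tolerance = 1e-6)
})

test_that("zero-match patterns are excluded with a warning", {
  model <- small_model()$model
  expect_warning(
    phi <- shapleySubstructures(model, "CCO",
                                patterns = alertPatterns()[c("hydroxyl",
                                                             "thiourea")]),
    "thiourea")
  expect_length(phi, 1)
})

test_that("alert aggregation reduces to per-molecule values on identical input", {
  model <- small_model()$model
  a <- attributeMolecule(model, "NC(=S)Nc1ccccc1OC")
  rep1 <- reportStructuralAlerts(list(a, a))
  expect_equal(rep1$mean_value,
               unname(sort(a@substructureValues, decreasing = TRUE)))
  expect_true(all(rep1$n_molecules == 2))
  # top_k larger than the vocabulary returns the full table
  rep2 <- reportStructuralAlerts(list(a), top_k = 100)
  expect_equal(nrow(rep2), length(a@substructureValues))
})

test_that("attribution maps serialize to JSON", {
  model <- small_model()$model
  a <- attributeMolecule(model, "NC(=S)Nc1ccccc1")
  tf <- tempfile(fileext = ".json")
  writeAttributions(list(a), tf)
  back <- jsonlite::read_json(tf)
  expect_equal(back[[1]]$smiles, a@smiles)
  expect_equal(length(back[[1]]$atom_weights), length(a@atomWeights))
})
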