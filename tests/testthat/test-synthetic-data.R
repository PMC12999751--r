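# Culture and structure-activity generators.

test_that("full persistent inhibition freezes nitrite at its addition-time value", {
  d <- simulateCulture(cultureSimParams(noise_sd = 0, inhibition_fraction = 1,
                                        recovery_halftime = Inf))
  trt <- d[d$treatment != "DMSO" & d$replicate == 1, ]
  post <- trt$nitrite_uM[trt$time_h >= trt$addition_time_h[1]]
  expect_lt(max(abs(diff(post))), 1e-5)
})

test_that("zero inhibition reproduces the control trajectory exactly (noise-free)", {
  d <- simulateCulture(cultureSimParams(noise_sd = 0, inhibition_fraction = 0))
  ctl <- d[d$treatment == "DMSO" & d$replicate == 1, "nitrite_uM"]
  trt <- d[d$treatment != "DMSO" & d$replicate == 1, "nitrite_uM"]
  expect_equal(trt, ctl, tolerance = 1e-8)
})

test_that("control follows the closed-form logistic solution", {
  p <- cultureSimParams(noise_sd = 0, inhibition_fraction = 0)
  d <- simulateCulture(p)
  ctl <- d[d$treatment == "DMSO" & d$replicate == 1, ]
  r <- 4 * p$max_rate / p$carrying_nitrite
  K <- p$carrying_nitrite; N0 <- p$baseline_nitrite
  expected <- K * N0 * exp(r * ctl$time_h) / (K + N0 * (exp(r * ctl$time_h) - 1))
  expect_equal(ctl$nitrite_uM, expected, tolerance = 1e-5)
})

test_that("partial inhibition scales the post-addition increment in the linear regime", {
  # at the logistic inflection the curve is locally linear, so a rate
  # multiplier (1 - f) scales the short-horizon increment by the same factor
  f <- 0.75
  p <- cultureSimParams(noise_sd = 0, inhibition_fraction = f,
                        addition_time = 114, timepoints = seq(0, 120, by = 6))
  d <- simulateCulture(p)
  inc <- function(tr) {
    x <- d[d$treatment == tr & d$replicate == 1, ]
    x$nitrite_uM[x$time_h == 120] - x$nitrite_uM[x$time_h == 114]
  }
  ratio <- inc(p$compound) / inc("DMSO")
  expect_equal(ratio, 1 - f, tolerance = 0.02)
})

test_that("noise-free control trajectories are non-decreasing and replicates differ only by noise", {
  d0 <- simulateCulture(cultureSimParams(noise_sd = 0))
  for (r in 1:3) {
    ctl <- d0[d0$treatment == "DMSO" & d0$replicate == r, "nitrite_uM"]
    expect_true(all(diff(ctl) >= -1e-9))
  }
  r1 <- d0[d0$replicate == 1, "nitrite_uM"]
  r2 <- d0[d0$replicate == 2, "nitrite_uM"]
  expect_equal(r1, r2)
})

test_that("the culture simulator is deterministic under seed and validates input", {
  a <- simulateCulture(cultureSimParams(seed = 42))
  b <- simulateCulture(cultureSimParams(seed = 42))
  expect_identical(a, b)
  c <- simulateCulture(cultureSimParams(seed = 43))
  expect_false(identical(a, c))
  expect_error(cultureSimParams(timepoints = c(0, 10, 10, 20)),
               "strictly increasing")
  expect_error(cultureSimParams(inhibition_fraction = 1.2), "\\[0, 1\\]")
  expect_error(cultureSimParams(noise_sd = -1), "noise_sd")
  expect_error(cultureSimParams(addition_time = 500), "addition_time")
})

test_that("SAR generation plants the pharmacophore exactly and labels via EC50", {
  p <- sarSimParams(n_compounds = 40, label_noise = 0, seed = 7)
  d <- generateSarDataset(p)
  expect_equal(nrow(d), 40)
  # noise-free: label equals the pattern-match indicator for every record
  match_ind <- vapply(d$smiles, function(s) {
    length(matchSubstructure(s, p$pharmacophore)) > 0
  }, logical(1), USE.NAMES = FALSE)
  expect_equal(d$label == 1L, match_ind)
  expect_equal(labelFromEc50(d$ec50_mg_per_L), d$label)
  # stratified generation: exact class split
  expect_equal(sum(d$planted), 20)
})

test_that("SAR generation is deterministic under seed and rejects bad scaffolds", {
  a <- generateSarDataset(sarSimParams(n_compounds = 15, seed = 9))
  b <- generateSarDataset(sarSimParams(n_compounds = 15, seed = 9))
  expect_identical(a, b)
  expect_error(sarSimParams(scaffold_library = c("c1ccccc1", "C1CC")), "C1CC")
  expect_error(sarSimParams(label_noise = 0.6), "label_noise")
})

test_that("assay and compound tables round-trip through CSV", {
  d <- simulateCulture(cultureSimParams(noise_sd = 2, seed = 5))
  tf <- tempfile(fileext = ".csv")
  writeAssayTable(d, tf)
  d2 <- readAssayTable(tf)
  expect_equal(d2$nitrite_uM, d$nitrite_uM, tolerance = 1e-12)

  cmp <- data.frame(id = c("a", "b"), name = c("x", "y"),
                    smiles = c("CCO", "c1ccccc1"),
                    ec50_mg_per_L = c("5", ">20"))
  tf2 <- tempfile(fileext = ".csv")
  writeCompoundTable(cmp, tf2)
  c2 <- readCompoundTable(tf2)
  expect_equal(c2$label, c(1L, 0L))

  ids <- c("m1", "m2"); smi <- c("CCO", "CCN")
  tf3 <- tempfile()
  writeSmilesFile(ids, smi, tf3, groupIds = c("g1", "g1"))
  s <- readSmilesFile(tf3)
  expect_equal(s$smiles, smi)
  expect_equal(s$group_id, c("g1", "g1"))
})
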