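# Graph-attention classifier: gradients, invariances, training behavior.

test_that("analytic gradients match finite differences", {
  cfg <- gatConfig(n_gat_layers = 2, hidden_dim = 8, n_attention_heads = 2,
                   dropout = 0, seed = 3)
  model <- buildGatModel(cfg)
  graphs <- lapply(c("CCO", "c1ccccc1", "CC(N)=O"), featurizeSmiles)
  batch <- BNIscreen:::build_batch(graphs, labels = c(1, 0, 1))
  w <- rep(1, 3)
  lossfun <- function(params) {
    fw <- BNIscreen:::gat_model_forward(params, cfg, batch)
    BNIscreen:::bce_loss(fw$logits, batch$y, w)$loss
  }
  fw <- BNIscreen:::gat_model_forward(model@params, cfg, batch)
  lo <- BNIscreen:::bce_loss(fw$logits, batch$y, w)
  bw <- BNIscreen:::gat_model_backward(model@params, cfg, batch, fw$caches,
                                       lo$dz)
  eps <- 1e-6
  set.seed(99)
  check_block <- function(get, set, grads) {
    p <- get(model@params)
    for (i in sample(length(p), min(4, length(p)))) {
      pa <- model@params; pa <- set(pa, i, p[i] + eps)
      pb <- model@params; pb <- set(pb, i, p[i] - eps)
      num <- (lossfun(pa) - lossfun(pb)) / (2 * eps)
      expect_lt(abs(num - grads[i]), 1e-5 + 1e-4 * abs(num))
    }
  }
  check_block(function(p) p$gat[[1]]$W,
              function(p, i, v) { p$gat[[1]]$W[i] <- v; p },
              bw$grads$gat[[1]]$W)
  check_block(function(p) p$gat[[2]]$a_src,
              function(p, i, v) { p$gat[[2]]$a_src[i] <- v; p },
              bw$grads$gat[[2]]$a_src)
  check_block(function(p) p$mhsa$Wq,
              function(p, i, v) { p$mhsa$Wq[i] <- v; p },
              bw$grads$mhsa$Wq)
  check_block(function(p) p$fc$W1,
              function(p, i, v) { p$fc$W1[i] <- v; p },
              bw$grads$fc$W1)
})

test_that("a one-node graph yields a finite logit", {
  model <- buildGatModel(gatConfig(hidden_dim = 16, n_attention_heads = 2,
                                   seed = 1))
  batch <- BNIscreen:::build_batch(list(featurizeSmiles("C")))
  fw <- BNIscreen:::gat_model_forward(model@params, model@config, batch)
  expect_true(is.finite(fw$logits))
})

test_that("initialization and predictions are deterministic under seed", {
  m1 <- buildGatModel(gatConfig(seed = 7))
  m2 <- buildGatModel(gatConfig(seed = 7))
  expect_identical(m1@params, m2@params)
  m3 <- buildGatModel(gatConfig(seed = 8))
  expect_false(identical(m1@params, m3@params))
})

test_that("predictions are invariant to atom ordering", {
  fx <- small_model()
  model <- fx$model
  for (s in fx$sar$smiles[1:6]) {
    g <- featurizeSmiles(s)
    n <- nrow(nodeFeatures(g))
    set.seed(n)
    perm <- sample(n)
    gp <- g
    gp@nodeFeatures <- g@nodeFeatures[perm, , drop = FALSE]
    inv <- order(perm)
    el <- g@edgeList
    el[, 1] <- inv[g@edgeList[, 1]]
    el[, 2] <- inv[g@edgeList[, 2]]
    gp@edgeList <- el
    p0 <- BNIscreen:::predict_graphs(model, list(g))
    p1 <- BNIscreen:::predict_graphs(model, list(gp))
    expect_lt(abs(log(p0 / (1 - p0)) - log(p1 / (1 - p1))), 1e-5)
  }
})

test_that("two SMILES spellings of a molecule receive the same prediction", {
  model <- small_model()$model
  pr <- predictActivity(model, c("OCC", "CCO"))
  expect_equal(pr$probability[1], pr$probability[2])
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
})

test_that("training fits a noiseless planted rule and is reproducible", {
  sar <- generateSarDataset(sarSimParams(n_compounds = 40, label_noise = 0,
                                         seed = 55))
  ds <- suppressWarnings(assembleDataset(sar, augment = FALSE))
  plan <- makeGroupSplits(ds, nRepeats = 1, seed = 56)
  cfg <- benchmarkConfig(seed = 57)
  t1 <- trainGat(buildGatModel(cfg), ds, assignments(plan, 1))
  expect_equal(t1@history$train_accuracy[nrow(t1@history)], 1.0)
  t2 <- trainGat(buildGatModel(cfg), ds, assignments(plan, 1))
  expect_identical(t1@history$train_loss[1], t2@history$train_loss[1])
  expect_identical(t1@history, t2@history)
})

test_that("training rejects degenerate partitions and mismatched features", {
  sar <- small_sar()[1:10, ]
  ds <- suppressWarnings(assembleDataset(sar, augment = FALSE))
  bad <- stats::setNames(rep("train", 10), unique(groupIds(ds)))
  model <- buildGatModel(benchmarkConfig(1))
  expect_error(trainGat(model, ds, bad), "empty")
  g <- ds@graphs[[1]]
  g@nodeFeatures <- cbind(g@nodeFeatures, extra = 0)
  g@atomMap <- g@atomMap  # keep validity: adjust map length unchanged
  expect_error(
    BNIscreen:::gat_model_forward(model@params, model@config,
                                  BNIscreen:::build_batch(list(g))),
    "feature dimension mismatch")
})

test_that("log P pretraining learns the surrogate and transfers only the trunk", {
  surro <- makeLogPSurrogate(n_molecules = 40, seed = 12)
  cfg <- gatConfig(n_gat_layers = 2, hidden_dim = 16, n_attention_heads = 2,
                   dropout = 0, learning_rate = 5e-3, seed = 13)
  model <- buildGatModel(cfg)
  st <- pretrainLogP(model, surro, epochs = 40)
  h <- st$history$loss
  expect_lt(mean(tail(h, 5)), mean(head(h, 5)))   # loss decreases

  cfg2 <- cfg; cfg2$pretrained_state <- st; cfg2$seed <- 14L
  ft <- buildGatModel(cfg2)
  expect_identical(ft@params$gat, st$trunk$gat)       # trunk transferred
  expect_identical(ft@params$mhsa, st$trunk$mhsa)
  expect_null(st$trunk$fc)                            # head never transferred
  expect_false(identical(ft@params$fc, model@params$fc))  # head re-initialized
  expect_equal(dim(ft@params$fc$W1), c(2 * 16, 16))
  # incompatible feature layout is refused
  st_bad <- st; st_bad$feature_version <- "bni-feat-0"
  cfg3 <- cfg; cfg3$pretrained_state <- st_bad
  expect_error(buildGatModel(cfg3), "feature set")
})

test_that("evaluation arithmetic matches confusion counts", {
  # constant-positive predictor on a balanced set scores 0.5
  per <- data.frame(repeat_index = 1:3, accuracy = c(0.8, 0.9, 1.0),
                    sensitivity = 1, specificity = 1, tp = 1, fp = 0,
                    tn = 1, fn = 0, n = 2)
  rep <- new("EvalReport", perRepeat = per, meanAccuracy = mean(per$accuracy),
             sdAccuracy = sd(per$accuracy), nRepeats = 3L)
  expect_equal(meanAccuracy(rep), 0.9)
  expect_error(new("EvalReport", perRepeat = per, meanAccuracy = 0.5,
                   sdAccuracy = 0.1, nRepeats = 3L), "mean")
})
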