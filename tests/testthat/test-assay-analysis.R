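# AOI statistics, group comparisons, clustering.

test_that("the standard curve maps absorbance to concentration", {
  std <- data.frame(concentration_uM = c(0, 25, 50, 100),
                    absorbance = c(0, 0.25, 0.5, 1))
  out <- absorbanceToNitrite(c(0, 0.5, 0.25), std)
  expect_equal(as.numeric(out), c(0, 50, 25), tolerance = 1e-10)
  expect_equal(attr(out, "r_squared"), 1)
  expect_error(absorbanceToNitrite(0.5, std[1:2, ]), "3 standards")
})

test_that("AOI identities: identical series 0%, flat treated 100%, 2/8 ratio 75%", {
  ctl <- tiny_series(c(0, 10, 18), "DMSO")
  expect_equal(computeAoi(tiny_series(c(0, 10, 18), "cpd"), ctl)@summaryEnd, 0)
  expect_equal(computeAoi(tiny_series(c(0, 10, 10), "cpd"), ctl)@summaryEnd, 100)
  expect_equal(computeAoi(tiny_series(c(0, 10, 12), "cpd"), ctl)@summaryEnd, 75)
})

test_that("AOI is not clipped: stimulation is negative, decline exceeds 100%", {
  ctl <- tiny_series(c(0, 10, 18), "DMSO")
  stim <- computeAoi(tiny_series(c(0, 10, 26), "cpd"), ctl)
  expect_equal(stim@summaryEnd, -100)
  decline <- computeAoi(tiny_series(c(0, 10, 6), "cpd"), ctl)
  expect_equal(decline@summaryEnd, 150)
})

test_that("AOI is undefined when the control is inactive", {
  ctl <- tiny_series(c(0, 10, 10.5), "DMSO")   # increment below epsilon
  expect_warning(prof <- computeAoi(tiny_series(c(0, 10, 10.2), "cpd"), ctl),
                 "undefined")
  expect_true(is.na(prof@summaryEnd))
  expect_false(any(prof@table$defined))
})

test_that("noise-free simulator inhibition is recovered by the AOI pipeline", {
  # persistent inhibition in the pre-saturation (near-linear) regime
  for (f in c(0.25, 0.75)) {
    prof <- aoi_from_assay(linear_regime_assay(f))
    expect_lt(abs(prof@summaryEnd - 100 * f), 2)
  }
  # monotone in the planted fraction
  ends <- vapply(c(0, 0.25, 0.5, 0.75, 1),
                 function(f) aoi_from_assay(linear_regime_assay(f))@summaryEnd,
                 numeric(1))
  expect_true(all(diff(ends) > 0))
})

test_that("group comparisons reproduce hand-computable statistics", {
  # identical values in all groups: Kruskal-Wallis statistic 0
  aoi <- data.frame(strain = "AOA_1", compound = rep(c("a", "b", "c"), each = 3),
                    dose_mg_per_L = 5, aoi = rep(50, 9))
  cg <- suppressWarnings(compareGroups(aoi))
  # all-tied data: the tie-corrected statistic degenerates to 0/0
  expect_true(is.nan(cg$kruskal$statistic) || cg$kruskal$statistic == 0)

  # complete AOA/AOB separation: rank-sum statistic at its extreme n1*n2
  sep <- data.frame(strain = rep(c("AOA_1", "AOB_1"), each = 6),
                    compound = rep(rep(c("a", "b"), each = 3), 2),
                    dose_mg_per_L = 5,
                    aoi = c(90, 95, 99, 85, 92, 97, 1, 3, 5, 2, 4, 6))
  cg_sep <- compareGroups(sep)
  expect_equal(cg_sep$wilcoxon_domain$W, 36)

  # Bonferroni adjustment is min(1, p * m) for the pairwise family
  set.seed(2)
  aoi2 <- data.frame(strain = "AOA_1",
                     compound = rep(c("a", "b", "c"), each = 4),
                     dose_mg_per_L = 5, aoi = rnorm(12))
  cg2 <- compareGroups(aoi2)
  expect_equal(cg2$dunn$p_adjusted,
               pmin(1, cg2$dunn$p_raw * nrow(cg2$dunn)))
  expect_error(compareGroups(aoi2[aoi2$compound == "a", ]), "at least 2")
})

test_that("domain comparison contrasts AOA against AOB per dose", {
  set.seed(3)
  aoi <- expand.grid(strain = c("AOA_1", "AOA_2", "AOB_1", "AOB_2"),
                     compound = c("a", "b", "c"), dose_mg_per_L = c(5, 20),
                     rep = 1:3)
  aoi$aoi <- rnorm(nrow(aoi), ifelse(grepl("AOA", aoi$strain), 70, 5), 8)
  cg <- compareGroups(aoi)
  expect_equal(nrow(cg$wilcoxon_domain), 2)
  expect_true(all(cg$wilcoxon_domain$p_value < 0.01))
  expect_equal(nrow(cg$shapiro), 8)   # 4 strains x 2 doses
})

test_that("identical rows merge first at distance zero", {
  m <- rbind(a = c(10, 20, 30), b = c(10, 20, 30), c = c(90, 10, 5),
             d = c(50, 60, 70))
  colnames(m) <- c("s1", "s2", "s3")
  res <- clusterHeatmap(m)
  expect_equal(res$row_hclust$height[1], 0)
  first_pair <- rownames(m)[sort(-res$row_hclust$merge[1, ])]
  expect_setequal(first_pair, c("a", "b"))
})

test_that("a two-block AOI matrix separates at the 2-cut (AOA/AOB analog)", {
  m <- rbind(cpd1 = c(100, 98, 0, 2), cpd2 = c(95, 100, 3, 0),
             cpd3 = c(2, 0, 97, 97), cpd4 = c(0, 4, 97, 99))
  colnames(m) <- c("AOA_1", "AOA_2", "AOB_1", "AOB_2")
  res <- clusterHeatmap(m)
  cut <- stats::cutree(res$col_hclust, 2)
  expect_equal(cut[["AOA_1"]], cut[["AOA_2"]])
  expect_equal(cut[["AOB_1"]], cut[["AOB_2"]])
  expect_false(cut[["AOA_1"]] == cut[["AOB_1"]])
  # brute-force oracle: all between-block distances exceed within-block ones
  d <- as.matrix(dist(t(m)))
  within <- c(d["AOA_1", "AOA_2"], d["AOB_1", "AOB_2"])
  between <- c(d["AOA_1", "AOB_1"], d["AOA_1", "AOB_2"],
               d["AOA_2", "AOB_1"], d["AOA_2", "AOB_2"])
  expect_true(min(between) > max(within))
  # Newick serialization round-trips through ape
  tr <- ape::read.tree(text = res$col_newick)
  expect_setequal(tr$tip.label, colnames(m))
})

test_that("single and complete linkage disagree as hand agglomeration predicts", {
  # points {0, 1, 2.1} on a line: single linkage merges {0,1} then chains
  # 2.1 at height 1.1; complete linkage merges {0,1} then joins at 2.1
  m <- cbind(x = c(0, 1, 2.1), y = 0)
  rownames(m) <- c("p0", "p1", "p2")
  single <- clusterHeatmap(cbind(m, m), linkage = "single")
  complete <- clusterHeatmap(cbind(m, m), linkage = "complete")
  # heights (on doubled coordinates distances scale by sqrt(2))
  expect_equal(single$row_hclust$height, sqrt(2) * c(1, 1.1), tolerance = 1e-9)
  expect_equal(complete$row_hclust$height, sqrt(2) * c(1, 2.1), tolerance = 1e-9)
})

test_that("clustering is invariant to input row/column order and imputes NAs", {
  m <- rbind(cpd1 = c(100, 98, 0, 2), cpd2 = c(95, 100, 3, 0),
             cpd3 = c(2, 0, 97, 97), cpd4 = c(0, 4, 97, 99))
  colnames(m) <- c("AOA_1", "AOA_2", "AOB_1", "AOB_2")
  a <- clusterHeatmap(m)
  b <- clusterHeatmap(m[c(3, 1, 4, 2), c(2, 4, 1, 3)])
  expect_identical(rownames(a$ordered), rownames(b$ordered))
  expect_identical(colnames(a$ordered), colnames(b$ordered))
  m2 <- m; m2["cpd1", "AOB_1"] <- NA
  res <- clusterHeatmap(m2)
  expect_true(res$imputed["cpd1", "AOB_1"])
  expect_equal(res$ordered["cpd1", "AOB_1"], 0)
})

test_that("aoiTable summarizes every condition of a long assay", {
  d1 <- simulateCulture(cultureSimParams(noise_sd = 2, seed = 5,
                                         strain = "AOA_1", compound = "c1"))
  d2 <- simulateCulture(cultureSimParams(noise_sd = 2, seed = 6,
                                         strain = "AOA_1", compound = "c2",
                                         inhibition_fraction = 0.2))
  tab <- aoiTable(rbind(d1, d2[d2$treatment != "DMSO", ]))
  expect_equal(nrow(tab), 2)
  expect_gt(tab$aoi_end[tab$compound == "c1"],
            tab$aoi_end[tab$compound == "c2"])
})
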