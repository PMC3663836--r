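test_that("Spearman dissimilarity matches hand-computed values", {
  x <- cbind(s1 = c(1, 2, 3, 4), s2 = c(1, 3, 2, 4), s3 = c(4, 3, 2, 1))
  rownames(x) <- paste0("f", 1:4)
  d <- spearmanDissimilarity(x, minOverlap = 4)
  expect_equal(diag(d), c(s1 = 0, s2 = 0, s3 = 0))
  expect_equal(d["s1", "s2"], 0.2)        # rho = 0.8 by hand
  expect_equal(d["s1", "s3"], 2)          # exactly reversed ranks
  expect_equal(d, t(d))
  ## invariance under strictly monotone transforms
  x2 <- x; x2[, "s2"] <- exp(x2[, "s2"])
  expect_equal(spearmanDissimilarity(x2, minOverlap = 4), d)
  ## minimum-overlap guard names the pair
  x3 <- x; x3[1:3, "s3"] <- NA
  expect_error(spearmanDissimilarity(x3, minOverlap = 2), "s1, s3")
})

test_that("Ward agglomeration equals brute-force Lance-Williams on small n", {
  set.seed(11)
  for (n in 4:6) {
    for (rep in 1:5) {
      pts <- matrix(rnorm(n * 2), n)
      d <- as.matrix(dist(pts))
      dimnames(d) <- list(letters[1:n], letters[1:n])
      tree <- wardHclust(d)
      oracle <- lw_ward_oracle(d)
      expect_equal(sort(tree$height), sort(oracle$heights),
                   tolerance = 1e-10)
      for (k in 2:(n - 1))
        expect_true(same_partition(stats::cutree(tree, k),
                                   oracle$partitions[[k]]))
    }
  }
  ## identical samples merge first at height zero
  d0 <- as.matrix(dist(c(0, 0, 5, 9)))
  dimnames(d0) <- list(letters[1:4], letters[1:4])
  t0 <- wardHclust(d0)
  expect_equal(t0$height[1], 0)
  expect_setequal(-t0$merge[1, ], 1:2)
  expect_error(wardHclust(matrix(0, 1, 1)), ">= 2")
})

test_that("planted well-separated groups are recovered at k = 2", {
  set.seed(7)
  x <- rbind(matrix(rnorm(40 * 6), 40), matrix(rnorm(40 * 6), 40))
  x[41:80, 4:6] <- x[41:80, 4:6] + 6
  colnames(x) <- paste0("s", 1:6)
  truth <- rep(c(1, 2), each = 3)
  lab <- cutClusters(wardHclust(spearmanDissimilarity(x)), 2)
  expect_true(same_partition(lab, truth))
})

test_that("cutClusters names k groups by size then member order", {
  d <- as.matrix(dist(c(1, 1.1, 1.2, 9, 9.1)))
  dimnames(d) <- list(paste0("s", 1:5), paste0("s", 1:5))
  tree <- wardHclust(d)
  expect_equal(as.integer(table(cutClusters(tree, 1))), 5L)
  expect_equal(sort(unname(cutClusters(tree, 5))), LETTERS[1:5])
  lab <- cutClusters(tree, 2)
  ## manual cut of the merge list: {s1,s2,s3} is the larger group -> "A"
  expect_equal(lab, c(s1 = "A", s2 = "A", s3 = "A", s4 = "B", s5 = "B"))
  expect_error(cutClusters(tree, 0), "k must be")
  expect_error(cutClusters(tree, 6), "k must be")
})

test_that("rank heatmap matrix ranks rows over present values", {
  x <- rbind(a = c(0.1, 0.3, 0.2), b = c(5, 5, 5), c = c(2, NA, 1))
  colnames(x) <- paste0("s", 1:3)
  rk <- rankHeatmapMatrix(x)
  expect_equal(rk["a", ], c(s1 = 1, s2 = 3, s3 = 2))
  expect_equal(rk["b", ], c(s1 = 2, s2 = 2, s3 = 2))
  expect_equal(rk["c", ], c(s1 = 2, s2 = NA, s3 = 1))
  ## rank invariance to the Ctmax convention: ranks of 2^(K - ct) do not
  ## depend on K and equal ranks of -ct
  ct <- matrix(rnorm(30, 28), 5, 6,
               dimnames = list(paste0("f", 1:5), paste0("s", 1:6)))
  expect_equal(rankHeatmapMatrix(2^(10 - ct)), rankHeatmapMatrix(-ct))
  expect_equal(rankHeatmapMatrix(2^(3 - ct)), rankHeatmapMatrix(-ct))
})

test_that("split drivers recover a planted block and stay empty on null", {
  sim <- simulateCohort(simConfig(seed = 5))
  expr <- preprocessCts(sim$ct)
  am <- sim$cases$case_id[sim$cases$genotype != "WT"]
  lab <- cutClusters(wardHclust(spearmanDissimilarity(expr[, am])), 2)
  drv <- identifySplitDrivers(expr[, am], lab)
  expect_gt(length(intersect(drv, sim$truth$block)), 40)
  expect_lt(length(setdiff(drv, sim$truth$block)), 3)
  ## identical group distributions -> empty set
  set.seed(21)
  nullx <- matrix(rnorm(100 * 12, 28), 100, 12,
                  dimnames = list(sprintf("f%03d", 1:100),
                                  sprintf("s%02d", 1:12)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = 2^(40 - nullx)))
  nullexpr <- new("MirExpression", se, ctMax = 40, ctMaxScope = "global")
  nulllab <- stats::setNames(rep(c("A", "B"), each = 6), colnames(nullx))
  expect_length(identifySplitDrivers(nullexpr, nulllab), 0)
  expect_error(identifySplitDrivers(nullexpr,
                                    stats::setNames(c("A", rep("B", 11)),
                                                    colnames(nullx))),
               ">= 2")
})

test_that("feature-block removal re-checks the matrix and records it", {
  sim <- simulateCohort(simConfig(seed = 5))
  expr <- preprocessCts(sim$ct)
  kept <- dropFeatureBlock(expr, sim$truth$block)
  expect_equal(nrow(kept), nrow(expr) - length(sim$truth$block))
  expect_setequal(S4Vectors::metadata(kept)$removed_block, sim$truth$block)
  expect_equal(dropFeatureBlock(expr, character(0)), expr)
  expect_error(dropFeatureBlock(expr, "no-such-miR"), "unknown feature")
  expect_error(dropFeatureBlock(expr, rownames(expr)), "empty matrix")
})

test_that("re-clustering without the block separates the cohort classes", {
  sim <- simulateCohort(simConfig(seed = 9))
  expr <- preprocessCts(sim$ct)
  kept <- dropFeatureBlock(expr, sim$truth$block)
  lab <- cutClusters(wardHclust(spearmanDissimilarity(kept)), 2)
  ## without the imprinted block the top split tracks SDHB status
  sdhb <- stats::setNames(sim$cases$sdhb_ihc, sim$cases$case_id)
  agree <- max(mean((lab == "A") == (sdhb[names(lab)] == "negative")),
               mean((lab == "B") == (sdhb[names(lab)] == "negative")))
  expect_gte(agree, 0.9)
})

test_that("dendrograms export as readable Newick", {
  d <- as.matrix(dist(c(1, 2, 8, 9)))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  f <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(wardHclust(d), f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, paste0("s", 1:4))
})
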