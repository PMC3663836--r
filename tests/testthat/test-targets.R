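toy_targets <- function() {
  TargetTable(data.frame(mirna_id = c("m1", "m2", "m3"),
                         gene_id = c("g1", "g3", "g2")),
              mirnaUniverse = paste0("m", 1:3),
              geneUniverse = paste0("g", 1:5))
}

test_that("diametric sets follow the scheme's directions", {
  mirna_de <- data.frame(
    comparison = "adult_mutant_vs_pediatric",
    feature_id = c("m1", "m2", "m3", "m4"),
    direction = c("higher_in_a", "higher_in_a", "higher_in_b",
                  "higher_in_a"),
    significant = c(TRUE, TRUE, TRUE, FALSE))
  gene_de <- data.frame(
    comparison = "adult_mutant_vs_pediatric",
    gene_id = c("g1", "g2", "g3", "g4"),
    direction = c("higher_in_b", "higher_in_b", "higher_in_b",
                  "higher_in_a"),
    significant = c(TRUE, TRUE, TRUE, TRUE))
  sch <- diametricSchemes()$genes_up_pediatric_vs_adult_mutant
  sets <- buildDiametricSets(mirna_de, gene_de, sch)
  ## hand selection: miRNAs lower in pediatric (higher_in_a, significant),
  ## genes higher in pediatric (higher_in_b, significant)
  expect_setequal(sets$mirnas_down, c("m1", "m2"))
  expect_setequal(sets$genes_up, c("g1", "g2", "g3"))
  ## no significant features -> both sets empty
  none <- mirna_de; none$significant <- FALSE
  gnone <- gene_de; gnone$significant <- FALSE
  empty <- buildDiametricSets(none, gnone, sch)
  expect_length(empty$mirnas_down, 0)
  expect_length(empty$genes_up, 0)
  ## absent comparison is an error
  sch2 <- diametricSchemes()$genes_up_mutant_vs_wt
  expect_error(buildDiametricSets(mirna_de, gene_de, sch2), "wt_vs_mutant")
})

test_that("interaction counting is exact and symmetric", {
  tt <- toy_targets()
  s <- list(comparison_name = "toy", mirnas_down = c("m1", "m2"),
            genes_up = c("g1", "g2"))
  expect_equal(countPredictedInteractions(s, tt), 1L)  # only (m1, g1)
  s$mirnas_down <- character()
  expect_equal(countPredictedInteractions(s, tt), 0L)
  full <- list(comparison_name = "toy", mirnas_down = mirnaUniverse(tt),
               genes_up = geneUniverse(tt))
  expect_equal(countPredictedInteractions(full, tt),
               nrow(targetPairs(tt)))
  bad <- list(comparison_name = "toy", mirnas_down = "m9", genes_up = "g1")
  expect_error(countPredictedInteractions(bad, tt), "m9")
  ## symmetry: counting via genes equals counting via miRNAs
  sym <- list(comparison_name = "toy", mirnas_down = c("m1", "m3"),
              genes_up = c("g1", "g2", "g3"))
  p <- targetPairs(tt)
  by_gene <- sum(vapply(sym$genes_up, function(g)
    sum(p$gene_id == g & p$mirna_id %in% sym$mirnas_down), 0L))
  expect_equal(countPredictedInteractions(sym, tt), by_gene)
})

test_that("permutation p equals exhaustive enumeration on a 5-gene universe", {
  tt <- toy_targets()
  s <- list(comparison_name = "toy", mirnas_down = c("m1", "m2"),
            genes_up = c("g1", "g3"))
  p_exact <- enum_enrichment_p(s, tt)          # all C(5,2) = 10 subsets
  res <- interactionEnrichment(s, tt, nullKind = "permutation",
                               nPermutations = 10000, seed = 13)
  expect_lt(abs(res$p_value - p_exact), 0.02)  # Monte-Carlo error bound
  ## with the seed fixed the result is bit-identical across runs
  res2 <- interactionEnrichment(s, tt, nullKind = "permutation",
                                nPermutations = 10000, seed = 13)
  expect_identical(res, res2)
  ## p is invariant to relabeling gene ids
  relab <- c(g1 = "x4", g2 = "x2", g3 = "x5", g4 = "x1", g5 = "x3")
  p2 <- targetPairs(tt); p2$gene_id <- unname(relab[p2$gene_id])
  tt2 <- TargetTable(p2, mirnaUniverse = mirnaUniverse(tt),
                     geneUniverse = unname(relab))
  s2 <- list(comparison_name = "toy", mirnas_down = s$mirnas_down,
             genes_up = unname(relab[s$genes_up]))
  expect_equal(enum_enrichment_p(s2, tt2), p_exact)
})

test_that("unenriched symmetric layouts are not called significant", {
  ## every gene targeted by the same number of set miRNAs
  pairs <- expand.grid(mirna_id = paste0("m", 1:2),
                       gene_id = paste0("g", 1:6),
                       stringsAsFactors = FALSE)
  tt <- TargetTable(pairs)
  s <- list(comparison_name = "sym", mirnas_down = c("m1", "m2"),
            genes_up = c("g1", "g2"))
  res <- interactionEnrichment(s, tt, nPermutations = 500, seed = 3)
  expect_gte(res$p_value, 0.5)
  expect_equal(res$observed, res$expected)
  hy <- interactionEnrichment(s, tt, nullKind = "hypergeometric")
  expect_equal(hy$expected, res$observed)
  expect_gte(hy$p_value, 0.5)
})

test_that("enrichment guards its preconditions", {
  tt <- toy_targets()
  s <- list(comparison_name = "toy", mirnas_down = "m1", genes_up = "g1")
  expect_error(interactionEnrichment(s, tt, nPermutations = 50), ">= 100")
  empty <- TargetTable(data.frame(mirna_id = character(),
                                  gene_id = character()),
                       mirnaUniverse = "m1", geneUniverse = character())
  expect_error(interactionEnrichment(s, empty), "empty universe")
})

test_that("planted enrichment is detected and the null level is held", {
  ## generator-planted 5x density inside the diametric sets
  sim <- simulateCohort(simConfig(seed = 6))
  sets <- list(comparison_name = "planted",
               mirnas_down = sim$truth$block,
               genes_up = sim$truth$genes_up_pediatric)
  res <- interactionEnrichment(sets, sim$targets, nPermutations = 2000,
                               seed = 4)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$observed, res$expected)
  ## permuting the miRNA side instead also detects it
  res_m <- interactionEnrichment(sets, sim$targets, nPermutations = 2000,
                                 seed = 4, permute = "mirnas")
  expect_lt(res_m$p_value, 0.05)
  ## type-I: density equal to background; margin = 0.05 + 2.6 se
  set.seed(19)
  null_rate <- mean(replicate(150, {
    pairs <- expand.grid(mirna_id = paste0("m", 1:10),
                         gene_id = paste0("g", 1:60),
                         stringsAsFactors = FALSE)
    pairs <- pairs[runif(nrow(pairs)) < 0.1, ]
    tt <- TargetTable(pairs, mirnaUniverse = paste0("m", 1:10),
                      geneUniverse = paste0("g", 1:60))
    s <- list(comparison_name = "null", mirnas_down = paste0("m", 1:4),
              genes_up = sample(paste0("g", 1:60), 15))
    interactionEnrichment(s, tt, nPermutations = 199)$p_value < 0.05
  }))
  expect_lte(null_rate, 0.05 + 2.6 * sqrt(0.05 * 0.95 / 150))
})
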