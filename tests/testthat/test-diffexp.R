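test_that("rank-sum p-values match exhaustive enumeration", {
  ## the textbook separated case: 2 of C(6,3) = 20 assignments as extreme
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  ## random tie-free inputs, n <= 6: exact mode equals full enumeration
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    a <- rnorm(n); b <- rnorm(m, sample(c(0, 2), 1))
    expect_equal(wilcoxonRankSum(a, b, mode = "exact")$p_value,
                 enum_wilcox_p(a, b), tolerance = 1e-12)
  }
  ## identical groups carry no evidence
  expect_gte(wilcoxonRankSum(c(1, 2, 3, 4), c(1, 2, 3, 4))$p_value, 0.9)
  expect_error(wilcoxonRankSum(1, c(1, 2)), ">= 2")
  expect_error(wilcoxonRankSum(c(1, 1, 2), c(1, 3, 4), mode = "exact"),
               "tie-free")
})

test_that("p-values are invariant under monotone transforms", {
  set.seed(5)
  a <- rnorm(9, 1); b <- rnorm(12)
  p1 <- wilcoxonRankSum(a, b)$p_value
  expect_equal(wilcoxonRankSum(2^(-a), 2^(-b))$p_value,
               wilcoxonRankSum(-a, -b)$p_value)
  expect_equal(wilcoxonRankSum(exp(a), exp(b))$p_value, p1)
})

test_that("the comparison roster enumerates the ten class contrasts", {
  sim <- simulateCohort(simConfig(seed = 2))
  labels <- stats::setNames(
    rep(c("B2a", "B2b"), length.out = nrow(sim$cases)),
    sim$cases$case_id)
  specs <- enumerateComparisons(sim$cases, labels, verbose = FALSE)
  expect_length(specs, 10L)
  expect_setequal(
    vapply(specs, `[[`, "", "name"),
    c("adult_mutant_vs_pediatric", "adult_wt_vs_pediatric_wt",
      "adult_vs_pediatric", "adult_wt_vs_adult_mutant", "wt_vs_mutant",
      "B2a_vs_B2b", "sdhb_pos_vs_neg", "fish_loss_vs_no_loss",
      "high_vs_low_risk", "dod_awd_vs_ned"))
  ## selectors are disjoint
  for (s in specs) expect_length(intersect(s$a, s$b), 0L)
  ## missing SDHB calls: comparison skipped with a log message, not error
  no_sdhb <- sim$cases
  no_sdhb$sdhb_ihc <- "not_tested"
  expect_message(specs2 <- enumerateComparisons(no_sdhb, labels),
                 "sdhb_pos_vs_neg")
  expect_length(specs2, 9L)
  ## adults only: pediatric-containing comparisons skipped
  adults <- sim$cases[sim$cases$age_class == "adult", ]
  specs3 <- enumerateComparisons(adults, NULL, verbose = FALSE)
  expect_false(any(grepl("pediatric", vapply(specs3, `[[`, "", "name"))))
})

test_that("planted shifts are recovered with no false positives", {
  ## 10 of 20 features shifted by 5 Ct, 15 vs 15 samples
  run_one <- function() {
    ct <- matrix(rnorm(20 * 30, 28), 20, 30,
                 dimnames = list(sprintf("f%02d", 1:20),
                                 sprintf("s%02d", 1:30)))
    ct[1:10, 1:15] <- ct[1:10, 1:15] + 5
    expr <- make_expr(ct)
    spec <- structure(list(name = "planted", a = colnames(ct)[1:15],
                           b = colnames(ct)[16:30]),
                      class = "ComparisonSpec")
    de <- compareClasses(expr, spec)
    hits <- de$feature_id[de$significant]
    setequal(hits, sprintf("f%02d", 1:10)) &&
      all(de$direction[de$significant] == "higher_in_b")  # +5 Ct = lower
  }
  set.seed(17)
  wins <- sum(replicate(60, run_one()))
  expect_gte(wins, 57)  # >= 95% of replicates
})

test_that("family size counts only testable features", {
  ct <- matrix(rnorm(4 * 8, 28), 4, 8,
               dimnames = list(paste0("f", 1:4), paste0("s", 1:8)))
  expr <- preprocessCts(make_ct(ct), minFraction = 0)
  ## feature absent in one whole group is dropped from the family
  SummarizedExperiment::assay(expr, "expr")["f1", 1:4] <- NA
  spec <- structure(list(name = "x", a = paste0("s", 1:4),
                         b = paste0("s", 5:8)), class = "ComparisonSpec")
  de <- compareClasses(expr, spec)
  expect_equal(nrow(de), 3L)
  expect_false("f1" %in% de$feature_id)
  ## Bonferroni uses m = 3: p_adjusted = min(1, 3 * p_raw)
  expect_equal(de$p_adjusted, pmin(1, de$p_raw * 3))
  expect_error(compareClasses(expr, structure(
    list(name = "bad", a = "zz", b = "s5"), class = "ComparisonSpec")),
    "bad")
})

test_that("Bonferroni adjustment is monotone and nested in alpha", {
  sim <- simulateCohort(simConfig(seed = 8))
  expr <- preprocessCts(sim$ct)
  specs <- enumerateComparisons(sim$cases, verbose = FALSE)
  de <- compareClasses(expr, specs[[1]])
  expect_true(all(de$p_adjusted >= de$p_raw))
  expect_true(all(de$p_adjusted <= 1 & de$p_raw > 0))
  de01 <- compareClasses(expr, specs[[1]], alpha = 0.01)
  expect_true(all(de01$feature_id[de01$significant] %in%
                    de$feature_id[de$significant]))
})

test_that("family-wise error stays at the nominal level under the null", {
  ## 300 null families of 20 features, 10 vs 10 samples; margin is the
  ## nominal 0.05 plus 2.6 binomial standard errors
  run_null <- function() {
    ct <- matrix(rnorm(20 * 20, 28), 20, 20,
                 dimnames = list(sprintf("f%02d", 1:20),
                                 sprintf("s%02d", 1:20)))
    expr <- preprocessCts(make_ct(ct))
    spec <- structure(list(name = "null", a = colnames(ct)[1:10],
                           b = colnames(ct)[11:20]),
                      class = "ComparisonSpec")
    any(compareClasses(expr, spec)$significant)
  }
  set.seed(29)
  fwer <- mean(replicate(300, run_null()))
  expect_lte(fwer, 0.05 + 2.6 * sqrt(0.05 * 0.95 / 300))
})
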