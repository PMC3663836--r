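## Wilcoxon rank-sum differential expression over the ten canonical GIST
## class comparisons, with Bonferroni family-wise control. The Bonferroni
## family is the set of features actually tested WITHIN each comparison
## (eligible feature sets differ between comparisons).

#' Two-sample Wilcoxon rank-sum test
#'
#' Thin, mode-controlled wrapper around [stats::wilcox.test]. In `"auto"`
#' mode the exact null distribution is enumerated when the smaller group
#' has at most 8 observations and the pooled data are tie-free; otherwise
#' the normal approximation with tie-variance and continuity corrections
#' is used. Because the statistic depends on ranks only, the p-value is
#' invariant under strictly monotone transforms of the pooled data.
#'
#' @param a,b numeric vectors, each with >= 2 observations.
#' @param mode `"auto"` (default), `"exact"`, or `"normal_approx"`.
#' @return list with elements `statistic` (W, rank-sum of `a` minus its
#'   minimum) and `p_value` (two-sided).
#' @export
wilcoxonRankSum <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("wilcoxonRankSum: each group needs >= 2 observations")
  has_ties <- anyDuplicated(c(a, b)) > 0L
  exact <- switch(mode,
    exact = TRUE,
    normal_approx = FALSE,
    auto = min(length(a), length(b)) <= 8L && !has_ties)
  if (exact && has_ties)
    stop("wilcoxonRankSum: exact mode requires tie-free data")
  ht <- stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                           correct = TRUE)
  list(statistic = unname(ht$statistic), p_value = min(1, ht$p.value))
}

## Feature-wise rank-sum DE between two sample groups of an expression
## matrix. Features with < 2 present values in either group are dropped
## from the family (and from m).
.wilcoxon_de_table <- function(x, samples_a, samples_b, alpha = 0.05,
                               mode = "auto", verbose = FALSE) {
  xa <- x[, samples_a, drop = FALSE]
  xb <- x[, samples_b, drop = FALSE]
  rows <- lapply(rownames(x), function(f) {
    va <- xa[f, ][!is.na(xa[f, ])]
    vb <- xb[f, ][!is.na(xb[f, ])]
    if (length(va) < 2L || length(vb) < 2L) return(NULL)
    wt <- wilcoxonRankSum(va, vb, mode = mode)
    rk <- rank(c(va, vb))
    data.frame(feature_id = f, n_a = length(va), n_b = length(vb),
               direction = if (mean(rk[seq_along(va)]) >=
                               mean(rk[-seq_along(va)]))
                 "higher_in_a" else "higher_in_b",
               p_raw = wt$p_value, stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (verbose && dropped)
    message(sprintf("wilcoxon DE: %d feature(s) dropped (< 2 present per group)",
                    dropped))
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(feature_id = character(), n_a = integer(),
                      n_b = integer(), direction = character(),
                      p_raw = numeric(), p_adjusted = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  m <- nrow(res)
  res$p_adjusted <- pmin(1, res$p_raw * m)
  res$significant <- res$p_adjusted < alpha
  rownames(res) <- NULL
  res
}

#' The ten canonical GIST class comparisons
#'
#' Builds the comparison roster over a case table (and, for the
#' B2a-vs-B2b contrast, a cluster labelling): 1) adult mutant vs
#' pediatric, 2) adult WT vs pediatric WT, 3) all adult vs pediatric,
#' 4) adult WT vs adult mutant, 5) all WT vs all mutant, 6) cluster B2a vs
#' B2b, 7) SDHB-immunopositive vs -immunonegative, 8) 14q32 loss vs no
#' loss, 9) adult high vs low risk, 10) adult outcome DOD/AWD vs no
#' evidence of disease. Comparisons whose groups are empty on the given
#' table (e.g. missing SDHB calls) are skipped with a logged reason, not
#' an error.
#'
#' @param cases validated case table from [readCaseTable()].
#' @param labels optional named cluster vector (case id -> cluster name)
#'   containing groups `"B2a"` and `"B2b"` for comparison 6.
#' @param verbose log skipped comparisons.
#' @return list of comparison specs; each is a list with `name`,
#'   `label_a`, `label_b` and disjoint case-id vectors `a`, `b`.
#' @export
enumerateComparisons <- function(cases, labels = NULL, verbose = TRUE) {
  id <- cases$case_id
  mutant <- cases$genotype %in% c("KIT", "PDGFRA", "BRAF")
  wt <- cases$genotype == "WT"
  adult <- cases$age_class == "adult"
  ped <- cases$age_class == "pediatric"
  def <- list(
    list(name = "adult_mutant_vs_pediatric", label_a = "adult mutant",
         label_b = "pediatric", a = id[adult & mutant], b = id[ped]),
    list(name = "adult_wt_vs_pediatric_wt", label_a = "adult WT",
         label_b = "pediatric WT", a = id[adult & wt], b = id[ped & wt]),
    list(name = "adult_vs_pediatric", label_a = "adult",
         label_b = "pediatric", a = id[adult], b = id[ped]),
    list(name = "adult_wt_vs_adult_mutant", label_a = "adult WT",
         label_b = "adult mutant", a = id[adult & wt],
         b = id[adult & mutant]),
    list(name = "wt_vs_mutant", label_a = "WT", label_b = "mutant",
         a = id[wt], b = id[mutant]),
    list(name = "B2a_vs_B2b", label_a = "B2a", label_b = "B2b",
         a = if (is.null(labels)) character() else
           names(labels)[labels == "B2a"],
         b = if (is.null(labels)) character() else
           names(labels)[labels == "B2b"]),
    list(name = "sdhb_pos_vs_neg", label_a = "SDHB positive",
         label_b = "SDHB negative", a = id[cases$sdhb_ihc == "positive"],
         b = id[cases$sdhb_ihc == "negative"]),
    list(name = "fish_loss_vs_no_loss", label_a = "14q32 loss",
         label_b = "no 14q32 loss", a = id[cases$fish_14q == "loss"],
         b = id[cases$fish_14q %in% c("diploid", "trisomy")]),
    list(name = "high_vs_low_risk", label_a = "high risk",
         label_b = "low risk", a = id[adult & cases$risk == "H"],
         b = id[adult & cases$risk == "L"]),
    list(name = "dod_awd_vs_ned", label_a = "DOD/AWD",
         label_b = "no evidence of disease",
         a = id[adult & cases$followup %in% c("DOD", "AWD")],
         b = id[adult & cases$followup == "WD"])
  )
  keep <- vapply(def, function(s) length(s$a) > 0L && length(s$b) > 0L,
                 logical(1))
  if (verbose)
    for (s in def[!keep])
      message("enumerateComparisons: skipping '", s$name,
              "' (empty group on this case table)")
  lapply(def[keep], function(s) structure(s, class = "ComparisonSpec"))
}

#' Differential expression for one class comparison
#'
#' Runs the feature-wise Wilcoxon rank-sum test between the two case
#' groups of a comparison spec, with Bonferroni correction over the
#' features actually tested in this comparison (those with >= 2 present
#' values in each group).
#'
#' @param expr a [MirExpression-class]; column names are case ids.
#' @param spec one element of [enumerateComparisons()] output.
#' @param alpha family-wise significance level (default 0.05).
#' @param correct if `FALSE`, call significance on the raw p-values
#'   (escape hatch; default `TRUE` uses the Bonferroni-adjusted ones).
#' @param mode test mode, see [wilcoxonRankSum()].
#' @param verbose log dropped features.
#' @return data.frame with columns `comparison`, `feature_id`, `n_a`,
#'   `n_b`, `direction` (`higher_in_a`/`higher_in_b`), `p_raw`,
#'   `p_adjusted`, `significant`.
#' @export
compareClasses <- function(expr, spec, alpha = 0.05, correct = TRUE,
                           mode = "auto", verbose = FALSE) {
  a <- intersect(spec$a, colnames(expr))
  b <- intersect(spec$b, colnames(expr))
  if (length(a) == 0L || length(b) == 0L)
    stop("compareClasses: selector matches no samples for comparison '",
         spec$name, "'")
  res <- .wilcoxon_de_table(assay(expr, "expr"), a, b, alpha = alpha,
                            mode = mode, verbose = verbose)
  if (!correct) res$significant <- res$p_raw < alpha
  if (nrow(res)) res <- cbind(comparison = spec$name, res)
  else res$comparison <- character()
  res
}

#' Run all available class comparisons
#'
#' @param expr a [MirExpression-class].
#' @param cases case table; `labels` as in [enumerateComparisons()].
#' @param labels optional cluster labels for the B2a/B2b contrast.
#' @param alpha,correct,mode forwarded to [compareClasses()].
#' @param verbose log skipped comparisons and family sizes.
#' @return single data.frame of per-comparison DE results (row-bound).
#' @export
runComparisons <- function(expr, cases, labels = NULL, alpha = 0.05,
                           correct = TRUE, mode = "auto", verbose = TRUE) {
  specs <- enumerateComparisons(cases, labels, verbose = verbose)
  specs <- Filter(function(s)
    length(intersect(s$a, colnames(expr))) >= 2L &&
    length(intersect(s$b, colnames(expr))) >= 2L, specs)
  out <- lapply(specs, function(s) {
    r <- compareClasses(expr, s, alpha = alpha, correct = correct,
                        mode = mode)
    if (verbose)
      message(sprintf("comparison %-28s family size m = %d, significant = %d",
                      s$name, nrow(r), sum(r$significant)))
    r
  })
  do.call(rbind, out)
}
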