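## Unsupervised clustering of sample expression profiles: Spearman rank
## dissimilarity (1 - rho, pairwise-complete with a minimum-overlap guard),
## Ward linkage, rank heatmap matrices, split-driver identification and
## feature-block removal.

#' Spearman rank dissimilarity between samples
#'
#' `d(i, j) = 1 - rho` where `rho` is Spearman's rank correlation between
#' the two samples' expression values over the features present in both
#' (average ranks for ties). Because the test statistic uses ranks only,
#' the result is invariant under any strictly monotone transform of either
#' sample, so Ct-scale and expression-scale inputs give the same tree.
#'
#' @param expr a [MirExpression-class], or a plain numeric matrix
#'   (features x samples).
#' @param minOverlap minimum number of jointly present features required
#'   per sample pair (default 10); fewer is an error naming the pair.
#' @return a symmetric matrix of dissimilarities in `[0, 2]` with zero
#'   diagonal, of class `dist`-compatible layout (plain matrix).
#' @export
spearmanDissimilarity <- function(expr, minOverlap = 10) {
  x <- if (is(expr, "MirExpression")) assay(expr, "expr") else as.matrix(expr)
  if (ncol(x) < 2L) stop("spearmanDissimilarity: need >= 2 samples")
  n_overlap <- crossprod(!is.na(x))
  short <- which(n_overlap < minOverlap, arr.ind = TRUE)
  short <- short[short[, 1] < short[, 2], , drop = FALSE]
  if (nrow(short))
    stop(sprintf(
      "spearmanDissimilarity: samples (%s, %s) share only %d features (< %d)",
      colnames(x)[short[1, 1]], colnames(x)[short[1, 2]],
      n_overlap[short[1, , drop = FALSE]], minOverlap))
  rho <- stats::cor(x, method = "spearman", use = "pairwise.complete.obs")
  d <- 1 - rho
  d[abs(d) < 1e-12] <- 0
  diag(d) <- 0
  d
}

#' Ward hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerates under Ward's minimum-variance criterion via the
#' Lance-Williams recurrence applied to the dissimilarities as given
#' (the classic `ward.D` dialect); set `squared = TRUE` to square the
#' dissimilarities before the update and take the square root of merge
#' heights (`ward.D2` dialect). Deterministic given the input.
#'
#' @param d symmetric dissimilarity matrix (e.g. from
#'   [spearmanDissimilarity()]) or a [stats::dist] object.
#' @param squared use the squared-dissimilarity (ward.D2) dialect.
#' @return an object of class [stats::hclust].
#' @export
wardHclust <- function(d, squared = FALSE) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-9))
      stop("wardHclust: dissimilarity matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  if (attr(d, "Size") < 2L) stop("wardHclust: need >= 2 samples")
  stats::hclust(d, method = if (squared) "ward.D2" else "ward.D")
}

#' Cut a dendrogram into k named clusters
#'
#' Cuts the `k - 1` highest merges and names the resulting groups `A`,
#' `B`, `C`, ... in decreasing size order, ties broken by the
#' lexicographically smallest member sample id.
#'
#' @param tree an [stats::hclust] object.
#' @param k number of clusters, `1 <= k <=` number of leaves.
#' @return named character vector: sample id -> cluster name.
#' @export
cutClusters <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1L || k > n) stop("cutClusters: k must be in [1, ", n, "]")
  grp <- stats::cutree(tree, k = k)
  sizes <- table(grp)
  first_member <- vapply(names(sizes), function(g)
    min(names(grp)[grp == as.integer(g)]), character(1))
  ord <- order(-as.integer(sizes), first_member)
  new_name <- stats::setNames(LETTERS[seq_len(k)], names(sizes)[ord])
  out <- unname(new_name[as.character(grp)])
  stats::setNames(out, names(grp))
}

#' Rank matrix for heatmap colouring
#'
#' Replaces each feature row by the ranks of its present values across
#' samples (average ranks for ties); missing cells stay missing. This is
#' the colouring scale used for expression heatmaps, and is invariant to
#' the Ctmax convention of the expression transform.
#'
#' @param expr a [MirExpression-class] or numeric matrix.
#' @return numeric matrix of within-feature ranks.
#' @export
rankHeatmapMatrix <- function(expr) {
  x <- if (is(expr, "MirExpression")) assay(expr, "expr") else as.matrix(expr)
  if (length(x) == 0L) stop("rankHeatmapMatrix: empty matrix")
  rk <- t(apply(x, 1L, function(r) {
    out <- rep(NA_real_, length(r))
    ok <- !is.na(r)
    out[ok] <- rank(r[ok], ties.method = "average")
    out
  }))
  dimnames(rk) <- dimnames(x)
  rk
}

#' Features driving a two-cluster split
#'
#' Tests every feature for differential expression between the two sample
#' groups of a k = 2 clustering (Wilcoxon rank-sum, Bonferroni over the
#' features tested) and returns the significant feature ids -- the
#' features whose differential expression explains the split.
#'
#' @param expr a [MirExpression-class].
#' @param labels named cluster vector with exactly 2 distinct values (from
#'   [cutClusters()]); names must match `colnames(expr)`.
#' @param alpha family-wise significance level (default 0.05).
#' @return character vector of feature ids.
#' @export
identifySplitDrivers <- function(expr, labels, alpha = 0.05) {
  groups <- unique(labels)
  if (length(groups) != 2L)
    stop("identifySplitDrivers: labels must define exactly 2 clusters")
  if (any(table(labels) < 2L))
    stop("identifySplitDrivers: each cluster must have >= 2 samples")
  res <- .wilcoxon_de_table(assay(expr, "expr"),
                            names(labels)[labels == groups[1]],
                            names(labels)[labels == groups[2]],
                            alpha = alpha)
  res$feature_id[res$significant]
}

#' Remove a feature block from an expression matrix
#'
#' Drops the given features (e.g. the dominant 14q32 imprinted miRNA
#' cluster) so the remaining structure can be re-clustered. The removal is
#' recorded in `metadata(.)$removed_block`.
#'
#' @param expr a [MirExpression-class].
#' @param block character vector of feature ids, all present in `expr`.
#' @return a [MirExpression-class] without the block's rows.
#' @export
dropFeatureBlock <- function(expr, block) {
  unknown <- setdiff(block, rownames(expr))
  if (length(unknown))
    stop("dropFeatureBlock: unknown feature(s): ",
         paste(utils::head(unknown, 3), collapse = ", "))
  if (length(block) == 0L) return(expr)
  if (length(block) >= nrow(expr))
    stop("dropFeatureBlock: removing all features leaves an empty matrix")
  out <- expr[!rownames(expr) %in% block, ]
  metadata(out)$removed_block <- union(metadata(out)$removed_block, block)
  validObject(out)
  out
}

#' Export a dendrogram as Newick
#'
#' @param tree an [stats::hclust] object.
#' @param path output file; merge heights become branch lengths.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
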