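## Independent small-instance oracles and fixture builders used across the
## suite. These deliberately re-derive results by brute force so the
## implementation under test is never checking itself.

suppressPackageStartupMessages(library(SummarizedExperiment))

## quick CtExperiment from a plain matrix
make_ct <- function(m, is_control = rep(FALSE, nrow(m)), stage = "raw") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("f%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  CtExperiment(m, isControl = is_control, stage = stage)
}

## exhaustive two-sided Wilcoxon rank-sum p-value: enumerate every
## C(n+m, n) assignment of the pooled tie-free values to group a
enum_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  idx <- utils::combn(length(pooled), n)
  u_all <- apply(idx, 2L, function(i) sum(rk[i]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

## brute-force Ward (ward.D dialect) agglomeration via the Lance-Williams
## recurrence applied to dissimilarities as given; returns merge heights
## and the leaf partition at every k
lw_ward_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  sizes <- rep(1, n)
  active <- rep(TRUE, n)
  heights <- numeric(0)
  partitions <- list()
  part_of <- function() {
    p <- integer(n)
    for (i in seq_along(clusters)) if (active[i]) p[clusters[[i]]] <- i
    p
  }
  partitions[[n]] <- part_of()
  while (sum(active) > 1L) {
    idx <- which(active)
    best <- c(NA, NA); best_d <- Inf
    for (ii in seq_along(idx)) for (jj in seq_len(ii - 1L)) {
      i <- idx[ii]; j <- idx[jj]
      if (d[i, j] < best_d) { best_d <- d[i, j]; best <- c(j, i) }
    }
    i <- best[1]; j <- best[2]
    ni <- sizes[i]; nj <- sizes[j]
    for (k in which(active)) {
      if (k == i || k == j) next
      nk <- sizes[k]
      d[i, k] <- d[k, i] <- ((ni + nk) * d[k, i] + (nj + nk) * d[k, j] -
                               nk * best_d) / (ni + nj + nk)
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- ni + nj
    active[j] <- FALSE
    heights <- c(heights, best_d)
    partitions[[sum(active)]] <- part_of()
  }
  list(heights = heights, partitions = partitions)
}

## exhaustive enrichment p over all gene subsets of the universe
enum_enrichment_p <- function(s, targets) {
  G <- geneUniverse(targets)
  ng <- length(s$genes_up)
  obs <- countPredictedInteractions(s, targets)
  subsets <- utils::combn(G, ng)
  counts <- apply(subsets, 2L, function(g)
    countPredictedInteractions(
      list(comparison_name = "enum", mirnas_down = s$mirnas_down,
           genes_up = g), targets))
  mean(counts >= obs)
}

## same-partition check up to label permutation
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

## wrap a Ct-scale matrix directly as relative expression (2^(40 - ct)),
## bypassing per-sample normalization
make_expr <- function(ct) {
  se <- SummarizedExperiment(assays = list(expr = 2^(40 - ct)))
  new("MirExpression", se, ctMax = 40, ctMaxScope = "global")
}
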