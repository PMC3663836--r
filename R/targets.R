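## Diametric miRNA:mRNA integration: pair significantly *down* miRNAs with
## significantly *up* genes from the same class contrast, count predicted
## binding interactions among them, and test over-representation against a
## chance null. The null the original analysis used is not specified, so
## two explicit nulls are provided: a gene-set resampling permutation null
## (degree-aware, default) and an analytic hypergeometric null in the
## flattened pair space (degree-blind); they bracket the unstated one.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' The diametric pairing schemes
#'
#' Named constants describing which class contrast each diametric
#' miRNA/gene pairing draws on and which direction qualifies each side:
#' genes up and miRNAs down in pediatric vs adult mutant; genes down and
#' miRNAs up in pediatric vs all adult; genes up and miRNAs down in mutant
#' vs WT; genes up and miRNAs down in WT vs mutant; genes up and miRNAs
#' down in pediatric vs adult WT. (The published scheme list states the
#' pediatric-vs-adult-mutant pairing twice; it is encoded once here.)
#'
#' Directions are expressed in the `higher_in_a`/`higher_in_b` convention
#' of the corresponding comparison in [enumerateComparisons()].
#'
#' @return named list of schemes, each with `name`, `comparison`,
#'   `gene_direction`, `mirna_direction`.
#' @export
diametricSchemes <- function() {
  mk <- function(name, comparison, gene_direction, mirna_direction)
    list(name = name, comparison = comparison,
         gene_direction = gene_direction, mirna_direction = mirna_direction)
  list(
    genes_up_pediatric_vs_adult_mutant = mk(
      "genes_up_pediatric_vs_adult_mutant", "adult_mutant_vs_pediatric",
      gene_direction = "higher_in_b", mirna_direction = "higher_in_a"),
    genes_down_pediatric_vs_adult = mk(
      "genes_down_pediatric_vs_adult", "adult_vs_pediatric",
      gene_direction = "higher_in_a", mirna_direction = "higher_in_b"),
    genes_up_mutant_vs_wt = mk(
      "genes_up_mutant_vs_wt", "wt_vs_mutant",
      gene_direction = "higher_in_b", mirna_direction = "higher_in_a"),
    genes_up_wt_vs_mutant = mk(
      "genes_up_wt_vs_mutant", "wt_vs_mutant",
      gene_direction = "higher_in_a", mirna_direction = "higher_in_b"),
    genes_up_pediatric_vs_adult_wt = mk(
      "genes_up_pediatric_vs_adult_wt", "adult_wt_vs_pediatric_wt",
      gene_direction = "higher_in_b", mirna_direction = "higher_in_a")
  )
}

#' Build the diametric miRNA / gene sets for a scheme
#'
#' Selects the significant miRNAs with the scheme's "down" direction and
#' the significant genes with the "up" direction from the two DE tables of
#' the same class contrast.
#'
#' @param mirnaDe miRNA DE table from [compareClasses()] /
#'   [runComparisons()] (columns `comparison`, `feature_id`, `direction`,
#'   `significant`).
#' @param geneDe gene DE table with columns `comparison`, `gene_id`,
#'   `direction`, `significant` (same direction convention).
#' @param scheme one element of [diametricSchemes()].
#' @return list of class `DiametricSets` with `comparison_name`,
#'   `mirnas_down`, `genes_up`.
#' @export
buildDiametricSets <- function(mirnaDe, geneDe, scheme) {
  if (!scheme$comparison %in% mirnaDe$comparison)
    stop("buildDiametricSets: comparison '", scheme$comparison,
         "' absent from miRNA DE table")
  if (!scheme$comparison %in% geneDe$comparison)
    stop("buildDiametricSets: comparison '", scheme$comparison,
         "' absent from gene DE table")
  m <- mirnaDe[mirnaDe$comparison == scheme$comparison &
                 mirnaDe$significant &
                 mirnaDe$direction == scheme$mirna_direction, ]
  g <- geneDe[geneDe$comparison == scheme$comparison &
                geneDe$significant &
                geneDe$direction == scheme$gene_direction, ]
  structure(list(comparison_name = scheme$name,
                 mirnas_down = unique(m$feature_id),
                 genes_up = unique(g$gene_id)),
            class = "DiametricSets")
}

#' Count predicted interactions between the diametric sets
#'
#' @param s a `DiametricSets` list (see [buildDiametricSets()]).
#' @param targets a [TargetTable-class].
#' @return integer: number of predicted pairs (m, g) with m in the miRNA
#'   set and g in the gene set. Symmetric in the two sets.
#' @export
countPredictedInteractions <- function(s, targets) {
  out_m <- setdiff(s$mirnas_down, mirnaUniverse(targets))
  out_g <- setdiff(s$genes_up, geneUniverse(targets))
  if (length(out_m) || length(out_g))
    stop("countPredictedInteractions: set id(s) outside declared universe: ",
         paste(utils::head(c(out_m, out_g), 3), collapse = ", "))
  p <- targetPairs(targets)
  sum(p$mirna_id %in% s$mirnas_down & p$gene_id %in% s$genes_up)
}

#' Over-representation of predicted interactions
#'
#' Tests whether the diametric sets contain more predicted miRNA:gene
#' interactions than expected by chance. Two nulls are available:
#' \describe{
#'   \item{permutation (default)}{gene sets of size `|genes_up|` are
#'     resampled uniformly without replacement from the gene universe with
#'     the miRNA set fixed; `p = (1 + #(null >= observed)) / (1 + n)`.
#'     Degree-aware: it conditions on the target degrees of the miRNA set.}
#'   \item{hypergeometric}{pair membership is treated as hypergeometric in
#'     the flattened pair space `miRNA set x gene universe`; degree-blind,
#'     but closed-form. Expected count is
#'     `|genes_up| / |gene universe| * sum(deg(m))` under both nulls.}
#' }
#'
#' @param s a `DiametricSets` list.
#' @param targets a [TargetTable-class] with non-empty universes.
#' @param nullKind `"permutation"` or `"hypergeometric"`.
#' @param nPermutations number of resamples (>= 100) for the permutation
#'   null.
#' @param seed integer seed making the permutation null reproducible
#'   (bit-identical across runs); the caller's RNG state is preserved.
#' @param permute which side to resample in the permutation null:
#'   `"genes"` (default) or `"mirnas"`.
#' @return list of class `EnrichmentResult`: `observed`, `expected`,
#'   `p_value`, `null_kind`, `n_permutations`, `seed`, set sizes.
#' @export
interactionEnrichment <- function(s, targets,
                                  nullKind = c("permutation",
                                               "hypergeometric"),
                                  nPermutations = 10000, seed = NULL,
                                  permute = c("genes", "mirnas")) {
  nullKind <- match.arg(nullKind)
  permute <- match.arg(permute)
  if (length(geneUniverse(targets)) == 0L ||
      length(mirnaUniverse(targets)) == 0L)
    stop("interactionEnrichment: empty universe")
  observed <- countPredictedInteractions(s, targets)
  p <- targetPairs(targets)
  G <- geneUniverse(targets)
  deg_set <- sum(p$mirna_id %in% s$mirnas_down)  # edges from set miRNAs
  expected <- length(s$genes_up) / length(G) * deg_set
  if (nullKind == "hypergeometric") {
    N <- length(s$mirnas_down) * length(G)
    n_draw <- length(s$mirnas_down) * length(s$genes_up)
    p_value <- if (N == 0L) 1 else
      stats::phyper(observed - 1, deg_set, N - deg_set, n_draw,
                    lower.tail = FALSE)
    return(structure(list(observed = observed, expected = expected,
                          p_value = min(1, p_value),
                          null_kind = "hypergeometric",
                          n_permutations = NA_integer_, seed = NA_integer_,
                          n_mirnas = length(s$mirnas_down),
                          n_genes = length(s$genes_up)),
                     class = "EnrichmentResult"))
  }
  if (nPermutations < 100)
    stop("interactionEnrichment: nPermutations must be >= 100")
  if (permute == "genes") {
    ## per-gene count of set-miRNAs targeting it, over the full universe
    k <- table(factor(p$gene_id[p$mirna_id %in% s$mirnas_down], levels = G))
    k <- as.numeric(k)
    n_set <- length(s$genes_up)
    null_counts <- .with_seed(seed, vapply(seq_len(nPermutations),
      function(i) sum(k[sample.int(length(G), n_set)]), numeric(1)))
  } else {
    M <- mirnaUniverse(targets)
    k <- table(factor(p$mirna_id[p$gene_id %in% s$genes_up], levels = M))
    k <- as.numeric(k)
    n_set <- length(s$mirnas_down)
    null_counts <- .with_seed(seed, vapply(seq_len(nPermutations),
      function(i) sum(k[sample.int(length(M), n_set)]), numeric(1)))
  }
  structure(list(observed = observed,
                 expected = mean(null_counts),
                 p_value = (1 + sum(null_counts >= observed)) /
                   (1 + nPermutations),
                 null_kind = "permutation",
                 n_permutations = as.integer(nPermutations),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 n_mirnas = length(s$mirnas_down),
                 n_genes = length(s$genes_up)),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(
    "Interaction enrichment (%s null): observed = %d, expected = %.2f, p = %.4g\n",
    x$null_kind, x$observed, x$expected, x$p_value))
  cat(sprintf("  sets: %d miRNAs x %d genes", x$n_mirnas, x$n_genes))
  if (x$null_kind == "permutation")
    cat(sprintf("; %d permutations, seed %s", x$n_permutations,
                as.character(x$seed)))
  cat("\n")
  invisible(x)
}
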