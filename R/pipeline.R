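## End-to-end orchestration: preprocess -> cluster -> differential
## expression -> diametric target enrichment -> imprinting summaries.
## Every stage logs its parameters and counts; a stage failure aborts
## with the stage name and cause.

#' Nested A/B/B1/B2/B2a/B2b cluster labels
#'
#' Presentation-layer naming over recursive two-way cuts: the full cohort
#' is cut at k = 2 into clusters A and B, B is re-clustered and cut into
#' B1 and B2, and B2 into B2a and B2b. Sub-clusters are only produced
#' while the parent has at least `minSize` samples.
#'
#' Naming follows the published semantics where possible: when
#' `orientFeatures` is given (a 14q32 block annotation, or the computed
#' split drivers), cluster A is the top cluster with *higher* mean rank
#' expression of those features (the block-expressing cluster); otherwise
#' A is the larger top cluster. B1 is the smaller B subcluster (the
#' silenced adult-mutant group in the study) and B2a the larger B2
#' subcluster; size ties break by smallest member id.
#'
#' @param expr a [MirExpression-class].
#' @param minOverlap forwarded to [spearmanDissimilarity()].
#' @param minSize smallest parent cluster that is further subdivided
#'   (default 4).
#' @param orientFeatures optional feature ids used to orient the A/B
#'   naming.
#' @return list with `top` (named vector, A/B), `nested` (named vector
#'   with the finest label per sample, e.g. A, B1, B2a, B2b) and `tree`
#'   (the full-cohort [stats::hclust]).
#' @export
nestedClusterLabels <- function(expr, minOverlap = 10, minSize = 4,
                                orientFeatures = NULL) {
  d <- spearmanDissimilarity(expr, minOverlap = minOverlap)
  tree <- wardHclust(d)
  top <- cutClusters(tree, 2)
  orientFeatures <- intersect(orientFeatures, rownames(expr))
  if (length(orientFeatures)) {
    rk <- rankHeatmapMatrix(expr)[orientFeatures, names(top), drop = FALSE]
    mean_rank <- tapply(colMeans(rk, na.rm = TRUE), top, mean)
    if (mean_rank[["A"]] < mean_rank[["B"]])
      top[] <- c(A = "B", B = "A")[top]
  }
  nested <- top
  subdivide <- function(parent, child_small, child_large) {
    ids <- names(nested)[nested == parent]
    if (length(ids) < minSize) return(NULL)
    sub_tree <- wardHclust(d[ids, ids])
    sub <- cutClusters(sub_tree, 2)  # "A" = larger subcluster
    nested[names(sub)] <<- ifelse(sub == "A", child_large, child_small)
  }
  subdivide("B", "B1", "B2")
  subdivide("B2", "B2b", "B2a")
  list(top = top, nested = nested, tree = tree)
}

#' Run the full analysis pipeline
#'
#' Executes the fixed stage order on a study bundle (as produced by
#' [simulateCohort()] or assembled from the readers): Ct pre-processing,
#' nested Spearman/Ward clustering, the class-comparison differential
#' expression roster, diametric miRNA:mRNA interaction enrichment (when a
#' gene DE table and target table are present), and 14q32
#' allelic-state/concordance summaries (when methylation calls are
#' present). Deterministic under a fixed `seed`.
#'
#' @param ct a raw [CtExperiment-class].
#' @param cases validated case table; `case_id` must match `colnames(ct)`.
#' @param methCalls optional methylation band-call table.
#' @param geneDe optional gene DE table (see [buildDiametricSets()]).
#' @param targets optional [TargetTable-class].
#' @param censorThreshold,minFraction,ctMaxScope pre-processing
#'   parameters.
#' @param minOverlap,alpha clustering / testing parameters.
#' @param scheme diametric scheme name (see [diametricSchemes()]).
#' @param nullKind,nPermutations enrichment null parameters.
#' @param expectedStates named map cluster -> expected allelic state for
#'   the concordance summary.
#' @param seed integer driving the enrichment permutations.
#' @param verbose log stage progress.
#' @return list of stage outputs: `expr`, `labels` (nested cluster
#'   labelling), `split_drivers`, `expr_noblock`, `labels_noblock`, `de`,
#'   `enrichment`, `allelic_states`, `concordance`, `cohort_counts`,
#'   `log` (character vector of stage messages).
#' @export
runPipeline <- function(ct, cases, methCalls = NULL, geneDe = NULL,
                        targets = NULL,
                        censorThreshold = 35, minFraction = 0.20,
                        ctMaxScope = "global", minOverlap = 10,
                        alpha = 0.05,
                        scheme = "genes_up_pediatric_vs_adult_mutant",
                        nullKind = "permutation", nPermutations = 10000,
                        expectedStates = c(A = "paternal_loss",
                                           B1 = "maternal_loss"),
                        seed = 1L, verbose = TRUE) {
  log <- character()
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    if (verbose) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  out <- list()
  out$expr <- stage("preprocess", {
    note("preprocess: censor > %g, detection >= %g, Ctmax scope %s",
         censorThreshold, minFraction, ctMaxScope)
    preprocessCts(ct, censorThreshold = censorThreshold,
                  minFraction = minFraction, ctMaxScope = ctMaxScope)
  })
  note("preprocess: %d of %d features retained", nrow(out$expr), nrow(ct))

  out$labels <- stage("cluster", {
    nestedClusterLabels(out$expr, minOverlap = minOverlap)
  })
  note("cluster: top split sizes %s",
       paste(table(out$labels$top), collapse = "/"))

  out$split_drivers <- stage("split_drivers", {
    identifySplitDrivers(out$expr, out$labels$top, alpha = alpha)
  })
  note("split_drivers: %d feature(s) drive the top split",
       length(out$split_drivers))

  if (length(out$split_drivers))
    out$labels <- stage("cluster", {
      ## re-orient naming so A is the cluster expressing the driver block
      nestedClusterLabels(out$expr, minOverlap = minOverlap,
                          orientFeatures = out$split_drivers)
    })

  out$expr_noblock <- stage("drop_block", {
    if (length(out$split_drivers) &&
        length(out$split_drivers) < nrow(out$expr))
      dropFeatureBlock(out$expr, out$split_drivers)
    else out$expr
  })
  out$labels_noblock <- stage("recluster", {
    nestedClusterLabels(out$expr_noblock, minOverlap = minOverlap)
  })

  out$de <- stage("diffexp", {
    runComparisons(out$expr, cases, labels = out$labels$nested,
                   alpha = alpha, verbose = verbose)
  })
  note("diffexp: %d comparisons, %d significant results",
       length(unique(out$de$comparison)), sum(out$de$significant))

  if (!is.null(geneDe) && !is.null(targets)) {
    out$enrichment <- stage("mirmatch", {
      sch <- diametricSchemes()[[scheme]]
      if (is.null(sch)) stop("unknown scheme: ", scheme)
      sets <- buildDiametricSets(out$de, geneDe, sch)
      interactionEnrichment(sets, targets, nullKind = nullKind,
                            nPermutations = nPermutations, seed = seed)
    })
    note("mirmatch: observed %d vs expected %.2f (p = %.4g, %s null)",
         out$enrichment$observed, out$enrichment$expected,
         out$enrichment$p_value, out$enrichment$null_kind)
  }

  if (!is.null(methCalls)) {
    out$allelic_states <- stage("imprint", classifyAllelicState(methCalls))
    out$concordance <- stage("imprint", {
      clusterConcordance(out$allelic_states, out$labels$nested,
                         expectedStates, verbose = verbose)
    })
  }

  out$cohort_counts <- stage("report", cohortCounts(cases))
  out$log <- log
  out
}
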