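## 14q32 (DLK1-DIO3) allelic-state interpretation. The imprinted miRNA
## cluster is expressed from the maternal allele only, so loss of the
## methylated paternal allele is expressionally silent while loss of the
## maternal allele abolishes expression. Methylation-specific PCR of the
## MEG3-promoter DMR yields a maternal (unmethylated) and a paternal
## (methylated) band; band presence/absence classifies the allelic state.

#' Classify 14q32 allelic state from MSP band calls
#'
#' Total over the 2 x 2 x 2 band/control space: both bands present gives
#' the normal imprinted pattern; only the maternal band, loss of the
#' (silent) paternal allele; only the paternal band, loss of the
#' (expressed) maternal allele; no band, or a failed bisulfite-conversion
#' control, is uninterpretable.
#'
#' @param calls data.frame from [readMethylationCalls()] (columns
#'   `case_id`, `maternal_band`, `paternal_band`, `conversion_control_ok`).
#' @return data.frame with columns `case_id`, `state` in
#'   `normal_pattern`, `paternal_loss`, `maternal_loss`, `uninterpretable`.
#' @export
classifyAllelicState <- function(calls) {
  state <- ifelse(!calls$conversion_control_ok, "uninterpretable",
           ifelse(calls$maternal_band & calls$paternal_band, "normal_pattern",
           ifelse(calls$maternal_band & !calls$paternal_band, "paternal_loss",
           ifelse(!calls$maternal_band & calls$paternal_band, "maternal_loss",
                  "uninterpretable"))))
  data.frame(case_id = calls$case_id, state = state, stringsAsFactors = FALSE)
}

#' Cluster-wise concordance with the expected allelic state
#'
#' For each cluster with an expectation (e.g. paternal loss in the
#' 14q32-expressing cluster A, maternal loss in the silenced cluster B1),
#' computes the fraction of interpretable tested cases whose classified
#' state matches. Cases without a cluster label are skipped with a log
#' entry; "normal pattern despite FISH loss" discordances are counted as
#' mismatches, never reclassified.
#'
#' @param states data.frame from [classifyAllelicState()].
#' @param labels named cluster vector (case id -> cluster name).
#' @param expected named character vector: cluster name -> expected state,
#'   e.g. `c(A = "paternal_loss", B1 = "maternal_loss")`.
#' @param verbose log skipped cases.
#' @return data.frame with columns `cluster`, `expected_state`, `n_tested`
#'   (interpretable cases), `n_matching`, `fraction` (`NA` when
#'   `n_tested == 0`), `pct` (fraction rounded to integer percent for
#'   display).
#' @export
clusterConcordance <- function(states, labels, expected, verbose = TRUE) {
  unlabeled <- setdiff(states$case_id, names(labels))
  if (length(unlabeled) && verbose)
    message("clusterConcordance: skipping unlabeled case(s): ",
            paste(unlabeled, collapse = ", "))
  st <- states[states$case_id %in% names(labels), ]
  out <- lapply(names(expected), function(cl) {
    in_cl <- st[labels[st$case_id] == cl, ]
    interp <- in_cl[in_cl$state != "uninterpretable", ]
    n <- nrow(interp)
    match_n <- sum(interp$state == expected[[cl]])
    data.frame(cluster = cl, expected_state = expected[[cl]],
               n_tested = n, n_matching = match_n,
               fraction = if (n) match_n / n else NA_real_,
               pct = if (n) round(100 * match_n / n) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' 14q32 FISH loss rate in a case subset
#'
#' @param cases case table from [readCaseTable()].
#' @param subset logical vector over rows of `cases`, or a predicate
#'   function of the case table returning one.
#' @return list with `n_tested` (FISH performed), `n_loss`, `fraction`
#'   (full precision) and `pct` (rounded to integer percent, the display
#'   convention).
#' @export
fishLossRate <- function(cases, subset = TRUE) {
  sel <- if (is.function(subset)) subset(cases) else rep(subset,
                                                         length.out = nrow(cases))
  tested <- cases[sel & cases$fish_14q != "not_tested", ]
  if (nrow(tested) == 0L)
    stop("fishLossRate: no FISH-tested cases in subset")
  n_loss <- sum(tested$fish_14q == "loss")
  list(n_tested = nrow(tested), n_loss = n_loss,
       fraction = n_loss / nrow(tested),
       pct = round(100 * n_loss / nrow(tested)))
}

#' Cohort genomic summary counts
#'
#' Tallies the case table: genotype counts (KIT/PDGFRA/BRAF/WT), SDHB
#' immunohistochemistry counts split by cohort class, and the class sizes
#' (adult mutant / adult WT / pediatric WT). Genotype categories are
#' mutually exclusive and exhaustive, so the genotype counts sum to the
#' row count.
#'
#' @param cases case table from [readCaseTable()].
#' @return list with `n_cases`, named vectors `genotype` and `class_size`,
#'   and a data.frame `sdhb` of SDHB status by class.
#' @export
cohortCounts <- function(cases) {
  genotype <- vapply(c("KIT", "PDGFRA", "BRAF", "WT"),
                     function(g) sum(cases$genotype == g), integer(1))
  cls <- ifelse(cases$age_class == "pediatric", "pediatric_wt",
                ifelse(cases$genotype == "WT", "adult_wt", "adult_mutant"))
  class_size <- vapply(c("adult_mutant", "adult_wt", "pediatric_wt"),
                       function(k) sum(cls == k), integer(1))
  if (nrow(cases)) {
    sdhb <- as.data.frame(table(class = cls, sdhb_ihc = cases$sdhb_ihc),
                          stringsAsFactors = FALSE)
    names(sdhb)[3] <- "n"
  } else {
    sdhb <- data.frame(class = character(), sdhb_ihc = character(),
                       n = integer(), stringsAsFactors = FALSE)
  }
  list(n_cases = nrow(cases), genotype = genotype, class_size = class_size,
       sdhb = sdhb)
}
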