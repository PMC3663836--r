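## Packaged study tables: the published case demographics (73 cases) and
## the per-comparison differentially expressed miRNA lists, transcribed
## row-for-row from the printed tables, plus a reconstruction of the
## methylation-assay outcomes from their reported aggregate counts.

#' Packaged GIST cohort case table
#'
#' The published demographics of the 73-case cohort (30 adult mutant,
#' 25 adult WT, 18 pediatric WT), transcribed verbatim: sex, age,
#' location, genotype/mutation, 14q32 FISH state, SDHB
#' immunohistochemistry, outcome, risk, histology and Carney-triad status.
#'
#' @return validated case data.frame (see [readCaseTable()]).
#' @examples
#' cohortCounts(gistCaseTable())$genotype
#' @export
gistCaseTable <- function() {
  readCaseTable(system.file("extdata", "tables1_3_cases.tsv",
                            package = "mirgist", mustWork = TRUE))
}

#' Packaged per-comparison DE miRNA lists
#'
#' The published lists of significantly differentially expressed miRNAs
#' for the class comparisons (comparison classes 1, 3-10), one row per
#' miRNA per comparison with the direction label, transcribed verbatim
#' (including one duplicated entry printed in the class-1 list).
#'
#' @return data.frame with columns `comparison_class`, `comparison`,
#'   `higher_in`, `mirna`.
#' @examples
#' table(gistDeMirnaTable()$comparison_class)
#' @export
gistDeMirnaTable <- function() {
  utils::read.table(system.file("extdata", "table4_de_mirnas.tsv",
                                package = "mirgist", mustWork = TRUE),
                    header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
}

#' Reconstructed 14q32 methylation-assay outcomes (synthetic case ids)
#'
#' Per-case MSP band calls and cluster labels reconstructed from the
#' reported aggregate outcomes of the methylation analysis: 12 tested
#' cases from the 14q32-expressing cluster A, 9 with loss of the paternal
#' (silent) allele and 3 with a normal pattern; 6 tested cases from the
#' silenced cluster B1, 5 with loss of the maternal allele and 1 normal.
#' The case-to-call assignment is not published, so case ids here are
#' synthetic placeholders; only the per-cluster counts are meaningful.
#'
#' @return list with `calls` (band-call data.frame as from
#'   [readMethylationCalls()]) and `labels` (named cluster vector).
#' @examples
#' with(clusterMethylationCalls(),
#'      clusterConcordance(classifyAllelicState(calls), labels,
#'                         c(A = "paternal_loss", B1 = "maternal_loss")))
#' @export
clusterMethylationCalls <- function() {
  ids <- c(sprintf("A%02d", 1:12), sprintf("B1_%02d", 1:6))
  ## paternal loss = maternal band only; maternal loss = paternal band only
  maternal <- c(rep(TRUE, 9), rep(TRUE, 3), rep(FALSE, 5), TRUE)
  paternal <- c(rep(FALSE, 9), rep(TRUE, 3), rep(TRUE, 5), TRUE)
  calls <- data.frame(case_id = ids, maternal_band = maternal,
                      paternal_band = paternal,
                      conversion_control_ok = TRUE,
                      stringsAsFactors = FALSE)
  labels <- stats::setNames(c(rep("A", 12), rep("B1", 6)), ids)
  list(calls = calls, labels = labels)
}

#' Emit the packaged fixture tables to a directory
#'
#' Copies `tables1_3_cases.tsv` and `table4_de_mirnas.tsv` to `outdir`;
#' re-emitting produces byte-identical files.
#'
#' @param outdir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
emitFixtureTables <- function(outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("emitFixtureTables: cannot create directory: ", outdir)
  files <- c("tables1_3_cases.tsv", "table4_de_mirnas.tsv")
  out <- file.path(outdir, files)
  for (i in seq_along(files)) {
    src <- system.file("extdata", files[i], package = "mirgist",
                       mustWork = TRUE)
    if (!file.copy(src, out[i], overwrite = TRUE))
      stop("emitFixtureTables: cannot write ", out[i])
  }
  invisible(out)
}
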