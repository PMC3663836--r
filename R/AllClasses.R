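#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

.CT_STAGES <- c("raw", "censored", "filtered", "mean_normalized")

#' Container for TaqMan array Ct values
#'
#' A `CtExperiment` holds a feature x sample grid of qPCR threshold-cycle
#' (Ct) values at a declared pre-processing stage. It extends
#' [SummarizedExperiment::SummarizedExperiment] with a single `"ct"` assay;
#' `rowData()` carries at least the logical column `is_control` (MammU6/RNU
#' internal-control flag) and optionally `pool` and block-membership
#' annotations; `colData()` holds per-case metadata.
#'
#' The `stage` slot enforces the fixed pre-processing order
#' raw -> censored -> filtered -> mean_normalized: each pre-processing
#' operation refuses input at the wrong stage.
#'
#' @slot stage character(1), one of `"raw"`, `"censored"`, `"filtered"`,
#'   `"mean_normalized"`.
#'
#' @seealso [censorCts()], [filterLowDetection()], [meanNormalize()],
#'   [toRelativeExpression()]
#' @export
setClass("CtExperiment",
  contains = "SummarizedExperiment",
  representation(stage = "character")
)

setValidity("CtExperiment", function(object) {
  msg <- character()
  if (length(object@stage) != 1L || !object@stage %in% .CT_STAGES)
    msg <- c(msg, sprintf("stage must be one of %s",
                          paste(.CT_STAGES, collapse = ", ")))
  if (!"ct" %in% assayNames(object))
    msg <- c(msg, "assay 'ct' is required")
  else {
    ct <- assay(object, "ct")
    present <- ct[!is.na(ct)]
    if (length(present) && any(!is.finite(present)))
      msg <- c(msg, "present Ct values must be finite")
    if (object@stage %in% c("raw", "censored") &&
        length(present) && any(present <= 0))
      msg <- c(msg, "raw/censored Ct values must be > 0")
    if (object@stage == "mean_normalized" && ncol(ct)) {
      mu <- colMeans(ct, na.rm = TRUE)
      mu <- mu[!is.nan(mu)]
      if (length(mu) && any(abs(mu) > 1e-9))
        msg <- c(msg, "per-sample mean of present values must be 0 (tol 1e-9)")
    }
  }
  if (!"is_control" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain logical column 'is_control'")
  if (length(msg)) msg else TRUE
})

#' Construct a CtExperiment
#'
#' @param ct numeric matrix of Ct values (features x samples), `NA` for
#'   undetected wells; dimnames required.
#' @param isControl logical vector flagging internal-control assays
#'   (recycled `FALSE` if omitted).
#' @param pool optional card-pool assignment per feature (`"A"`/`"B"`).
#' @param colData optional [S4Vectors::DataFrame] of per-case metadata.
#' @param stage pre-processing stage of the values, default `"raw"`.
#' @return a [CtExperiment-class] object.
#' @examples
#' ct <- matrix(c(25, 30, 36, 28), 2, 2,
#'              dimnames = list(c("miR-1", "miR-2"), c("S1", "S2")))
#' CtExperiment(ct)
#' @export
CtExperiment <- function(ct, isControl = NULL, pool = NULL, colData = NULL,
                         stage = "raw") {
  ct <- as.matrix(ct)
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("ct matrix must have feature and sample dimnames")
  if (anyDuplicated(rownames(ct))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(ct))) stop("duplicate sample ids")
  if (is.null(isControl)) isControl <- rep(FALSE, nrow(ct))
  rd <- DataFrame(is_control = as.logical(isControl), row.names = rownames(ct))
  if (!is.null(pool)) rd$pool <- pool
  if (is.null(colData))
    colData <- DataFrame(row.names = colnames(ct))
  se <- SummarizedExperiment(assays = list(ct = ct), rowData = rd,
                             colData = colData)
  new("CtExperiment", se, stage = stage)
}

#' Container for normalized relative miRNA expression
#'
#' Holds relative expression 2^(Ctmax - Ct) derived from a mean-normalized
#' [CtExperiment-class]. The `ctMax` slot records the reference maximum
#' normalized Ct; with the default global scope every present value is >= 1
#' and the minimum equals 1 at the cell that held Ctmax.
#'
#' @slot ctMax numeric; the reference maximum (length 1 for global scope,
#'   one per feature for per-feature scope).
#' @slot ctMaxScope `"global"` or `"feature"`.
#' @export
setClass("MirExpression",
  contains = "SummarizedExperiment",
  representation(ctMax = "numeric", ctMaxScope = "character")
)

setValidity("MirExpression", function(object) {
  msg <- character()
  if (!"expr" %in% assayNames(object))
    msg <- c(msg, "assay 'expr' is required")
  else {
    x <- assay(object, "expr")
    present <- x[!is.na(x)]
    if (length(present) && any(present <= 0))
      msg <- c(msg, "relative expression must be positive")
  }
  if (!object@ctMaxScope %in% c("global", "feature"))
    msg <- c(msg, "ctMaxScope must be 'global' or 'feature'")
  if (length(msg)) msg else TRUE
})

#' Predicted miRNA-to-gene target pairs over declared universes
#'
#' Wraps a TargetScan-style table of predicted miRNA:mRNA binding pairs
#' together with the background universes the enrichment test conditions
#' on (all measured-and-expressed miRNAs / genes, not the genome).
#'
#' @slot pairs data.frame with columns `mirna_id`, `gene_id`; unique rows.
#' @slot mirnaUniverse character vector of eligible miRNA ids.
#' @slot geneUniverse character vector of eligible gene ids.
#' @export
setClass("TargetTable",
  representation(pairs = "data.frame", mirnaUniverse = "character",
                 geneUniverse = "character")
)

setValidity("TargetTable", function(object) {
  msg <- character()
  p <- object@pairs
  if (!all(c("mirna_id", "gene_id") %in% names(p)))
    msg <- c(msg, "pairs must have columns mirna_id, gene_id")
  else {
    if (anyDuplicated(p)) msg <- c(msg, "duplicate target pairs")
    if (!all(p$mirna_id %in% object@mirnaUniverse))
      msg <- c(msg, "pair miRNA id outside declared universe")
    if (!all(p$gene_id %in% object@geneUniverse))
      msg <- c(msg, "pair gene id outside declared universe")
  }
  if (anyDuplicated(object@mirnaUniverse) || anyDuplicated(object@geneUniverse))
    msg <- c(msg, "universes must be duplicate-free")
  if (length(msg)) msg else TRUE
})

#' Construct a TargetTable
#'
#' @param pairs data.frame with columns `mirna_id`, `gene_id`.
#' @param mirnaUniverse,geneUniverse background universes; default to the
#'   ids present in `pairs`.
#' @return a [TargetTable-class].
#' @export
TargetTable <- function(pairs,
                        mirnaUniverse = unique(pairs$mirna_id),
                        geneUniverse = unique(pairs$gene_id)) {
  pairs <- unique(as.data.frame(pairs)[, c("mirna_id", "gene_id")])
  pairs$mirna_id <- as.character(pairs$mirna_id)
  pairs$gene_id <- as.character(pairs$gene_id)
  rownames(pairs) <- NULL
  new("TargetTable", pairs = pairs,
      mirnaUniverse = as.character(mirnaUniverse),
      geneUniverse = as.character(geneUniverse))
}

## ---- accessors -------------------------------------------------------------

#' @describeIn CtExperiment-class pre-processing stage of the Ct values.
#' @param x a `CtExperiment`.
#' @export
ctStage <- function(x) x@stage

#' @describeIn MirExpression-class the reference maximum normalized Ct.
#' @param x a `MirExpression`.
#' @export
ctMax <- function(x) x@ctMax

#' @describeIn TargetTable-class the pair table.
#' @param x a `TargetTable`.
#' @export
targetPairs <- function(x) x@pairs

#' @describeIn TargetTable-class declared miRNA universe.
#' @export
mirnaUniverse <- function(x) x@mirnaUniverse

#' @describeIn TargetTable-class declared gene universe.
#' @export
geneUniverse <- function(x) x@geneUniverse

setMethod("show", "CtExperiment", function(object) {
  cat(sprintf("CtExperiment: %d features x %d samples [stage: %s]\n",
              nrow(object), ncol(object), object@stage))
  ct <- assay(object, "ct")
  cat(sprintf("  missing wells: %d (%.1f%%); control assays: %d\n",
              sum(is.na(ct)), 100 * mean(is.na(ct)),
              sum(rowData(object)$is_control)))
})

setMethod("show", "MirExpression", function(object) {
  cat(sprintf("MirExpression: %d features x %d samples [Ctmax %s: %.4g]\n",
              nrow(object), ncol(object), object@ctMaxScope,
              if (object@ctMaxScope == "global") object@ctMax else NA))
  blk <- metadata(object)$removed_block
  if (!is.null(blk))
    cat(sprintf("  removed feature block: %d features\n", length(blk)))
})

setMethod("show", "TargetTable", function(object) {
  cat(sprintf("TargetTable: %d predicted pairs over %d miRNAs x %d genes\n",
              nrow(object@pairs), length(object@mirnaUniverse),
              length(object@geneUniverse)))
})
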