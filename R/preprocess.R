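## Four-step Ct pre-processing chain. Order is fixed and enforced through
## the stage slot: censor -> detection filter -> per-sample mean
## normalization -> relative expression. Tolerance for floating
## comparisons is 1e-9 absolute throughout.

.check_stage <- function(m, expected, op) {
  if (!is(m, "CtExperiment"))
    stop(op, ": input must be a CtExperiment")
  if (ctStage(m) != expected)
    stop(sprintf("%s: input must be at stage '%s' (got '%s')",
                 op, expected, ctStage(m)))
}

#' Censor high-Ct noise
#'
#' Ct values strictly greater than the threshold are regarded as
#' amplification noise and set to missing; values at or below the
#' threshold are unchanged. Censoring an already-censored matrix at the
#' same threshold is the identity.
#'
#' @param m a [CtExperiment-class] at stage `"raw"` (or `"censored"`, for
#'   idempotent re-application).
#' @param threshold Ct above which a well is treated as undetected
#'   (default 35).
#' @param verbose log the number of censored wells.
#' @return a `CtExperiment` at stage `"censored"`.
#' @export
censorCts <- function(m, threshold = 35, verbose = FALSE) {
  if (!is(m, "CtExperiment")) stop("censorCts: input must be a CtExperiment")
  if (!ctStage(m) %in% c("raw", "censored"))
    stop("censorCts: input must be at stage 'raw' (got '", ctStage(m), "')")
  ct <- assay(m, "ct")
  hit <- !is.na(ct) & ct > threshold
  ct[hit] <- NA_real_
  if (verbose)
    message(sprintf("censorCts: %d wells > %g set to missing", sum(hit),
                    threshold))
  out <- m
  assay(out, "ct", withDimnames = FALSE) <- ct
  out@stage <- "censored"
  validObject(out)
  out
}

#' Drop rarely detected features and internal controls
#'
#' A feature is retained iff it is detected (present after censoring) in at
#' least `minFraction` of samples; the comparison is `>=`, so a feature
#' detected in exactly 20% of samples survives the default filter.
#' Internal-control assays (`is_control`) are removed unconditionally
#' before analysis.
#'
#' @param m a [CtExperiment-class] at stage `"censored"`.
#' @param minFraction minimum detected fraction (default 0.20).
#' @param verbose log the number of features removed.
#' @return a `CtExperiment` at stage `"filtered"`.
#' @export
filterLowDetection <- function(m, minFraction = 0.20, verbose = FALSE) {
  .check_stage(m, "censored", "filterLowDetection")
  if (ncol(m) == 0L) stop("filterLowDetection: matrix has zero samples")
  ct <- assay(m, "ct")
  detected <- rowMeans(!is.na(ct))
  ctl <- rowData(m)$is_control
  keep <- detected >= minFraction - 1e-9 & !ctl
  if (verbose)
    message(sprintf(
      "filterLowDetection: removed %d low-detection features, %d controls",
      sum(!keep & !ctl), sum(ctl)))
  out <- m[keep, ]
  out@stage <- "filtered"
  validObject(out)
  out
}

#' Per-sample mean normalization
#'
#' Subtracts from each present Ct the mean of that sample's present Ct
#' values, so every sample's mean normalized Ct is zero. Missing values
#' stay missing and do not enter the mean.
#'
#' @param m a [CtExperiment-class] at stage `"filtered"`.
#' @return a `CtExperiment` at stage `"mean_normalized"`.
#' @export
meanNormalize <- function(m) {
  .check_stage(m, "filtered", "meanNormalize")
  ct <- assay(m, "ct")
  n_present <- colSums(!is.na(ct))
  if (any(n_present == 0L))
    stop("meanNormalize: sample(s) with no present values: ",
         paste(colnames(ct)[n_present == 0L], collapse = ", "))
  mu <- colMeans(ct, na.rm = TRUE)
  ct <- sweep(ct, 2L, mu, "-")
  out <- m
  assay(out, "ct", withDimnames = FALSE) <- ct
  out@stage <- "mean_normalized"
  validObject(out)
  out
}

#' Convert normalized Ct to relative expression
#'
#' Applies `expression = 2^(Ctmax - Ct)` to the mean-normalized matrix,
#' where `Ctmax` is the maximum present normalized Ct. With the default
#' global scope there is a single reference maximum, every present value
#' is `>= 1`, and the minimum expression (exactly 1) is attained at the
#' cell holding `Ctmax`. Per-feature scope uses each feature's own row
#' maximum instead.
#'
#' @param m a [CtExperiment-class] at stage `"mean_normalized"`.
#' @param ctMaxScope `"global"` (one reference for the whole matrix,
#'   default) or `"feature"` (row-wise reference).
#' @return a [MirExpression-class].
#' @export
toRelativeExpression <- function(m, ctMaxScope = c("global", "feature")) {
  .check_stage(m, "mean_normalized", "toRelativeExpression")
  ctMaxScope <- match.arg(ctMaxScope)
  ct <- assay(m, "ct")
  if (all(is.na(ct))) stop("toRelativeExpression: no present values")
  if (ctMaxScope == "global") {
    cmax <- max(ct, na.rm = TRUE)
    expr <- 2^(cmax - ct)
  } else {
    cmax <- apply(ct, 1L, function(x)
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
    expr <- 2^(cmax - ct)
  }
  se <- SummarizedExperiment(assays = list(expr = expr),
                             rowData = rowData(m), colData = colData(m))
  out <- new("MirExpression", se, ctMax = unname(cmax),
             ctMaxScope = ctMaxScope)
  validObject(out)
  out
}

#' Run the full Ct pre-processing chain
#'
#' Convenience wrapper: [censorCts()] then [filterLowDetection()] then
#' [meanNormalize()] then [toRelativeExpression()].
#'
#' @param m a [CtExperiment-class] at stage `"raw"`.
#' @param censorThreshold,minFraction,ctMaxScope forwarded to the stages.
#' @param verbose log per-stage counts.
#' @return a [MirExpression-class].
#' @export
preprocessCts <- function(m, censorThreshold = 35, minFraction = 0.20,
                          ctMaxScope = "global", verbose = FALSE) {
  m <- censorCts(m, threshold = censorThreshold, verbose = verbose)
  m <- filterLowDetection(m, minFraction = minFraction, verbose = verbose)
  m <- meanNormalize(m)
  toRelativeExpression(m, ctMaxScope = ctMaxScope)
}
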