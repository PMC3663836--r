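## Table ingestion with strict validation. All pipeline inputs are plain
## CSV/TSV with a header row; missing-value tokens common in qPCR exports
## ("NA", "", "Undetermined", "ND") are recognised explicitly -- anything
## else is an error, never a silent coercion.

.DEFAULT_MISSING_TOKENS <- c("NA", "", "Undetermined", "ND")

.read_delim <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim))
    delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL, stringsAsFactors = FALSE,
                    comment.char = "", fill = FALSE)
}

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(miss, collapse = ", ")))
}

#' Read a long-format Ct table
#'
#' Reads a long CSV/TSV of raw qPCR threshold cycles with columns
#' `feature_id`, `sample_id`, `ct`, and optionally `pool` (card A/B) and
#' `is_control` (internal-control flag). Each (feature, sample) key must be
#' unique. Ct cells holding a recognised missing-value token become `NA`;
#' any other non-numeric cell is a row-level parse error.
#'
#' @param path file path.
#' @param schema named character vector mapping canonical column names
#'   (`feature_id`, `sample_id`, `ct`, `pool`, `is_control`) to the file's
#'   column names, for files with non-standard headers.
#' @param delim field delimiter; inferred from the extension if `NULL`.
#' @param missingTokens character vector of Ct tokens read as missing.
#' @param strict if `TRUE`, missing-value tokens other than a truly empty
#'   cell are parse errors rather than `NA` (undetected wells must then be
#'   absent from the file).
#' @param as return a wide [CtExperiment-class] (default) or the validated
#'   long `"records"` data.frame.
#' @return a `CtExperiment` at stage `"raw"`, or a data.frame.
#' @export
readCtTable <- function(path, schema = NULL, delim = NULL,
                        missingTokens = .DEFAULT_MISSING_TOKENS,
                        strict = FALSE,
                        as = c("CtExperiment", "records")) {
  as <- match.arg(as)
  df <- .read_delim(path, delim)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(df))
        stop(sprintf("Ct table: schema column '%s' not found", schema[[canon]]))
      names(df)[names(df) == schema[[canon]]] <- canon
    }
  }
  .require_cols(df, c("feature_id", "sample_id", "ct"), "Ct table")
  ct_chr <- trimws(df$ct)
  is_missing <- ct_chr %in% missingTokens
  if (strict && any(is_missing & ct_chr != ""))
    stop(sprintf("Ct table: non-numeric Ct token '%s' at data row %d (strict mode)",
                 ct_chr[is_missing & ct_chr != ""][1],
                 which(is_missing & ct_chr != "")[1]))
  ct <- suppressWarnings(as.numeric(ct_chr))
  bad <- !is_missing & is.na(ct)
  if (any(bad))
    stop(sprintf("Ct table: unparseable Ct value '%s' at data row %d",
                 ct_chr[bad][1], which(bad)[1]))
  ct[is_missing] <- NA_real_
  if (any(!is.na(ct) & (!is.finite(ct) | ct <= 0)))
    stop("Ct table: present Ct values must be finite and > 0")
  key <- paste(df$feature_id, df$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("Ct table: duplicate (feature, sample) key: (%s, %s)",
                 d$feature_id, d$sample_id))
  }
  rec <- data.frame(
    feature_id = df$feature_id, sample_id = df$sample_id, ct = ct,
    pool = if ("pool" %in% names(df)) df$pool else NA_character_,
    is_control = if ("is_control" %in% names(df))
      .parse_logical(df$is_control, "is_control") else FALSE,
    stringsAsFactors = FALSE)
  if (!all(is.na(rec$pool)) && !all(rec$pool %in% c("A", "B")))
    stop("Ct table: pool must be 'A' or 'B'")
  if (as == "records") return(rec)
  ctExperimentFromRecords(rec)
}

#' Pivot long Ct records to a CtExperiment
#'
#' @param records data.frame as returned by
#'   `readCtTable(..., as = "records")`.
#' @return a [CtExperiment-class] at stage `"raw"`; wells absent from the
#'   long table are `NA`.
#' @export
ctExperimentFromRecords <- function(records) {
  feats <- unique(records$feature_id)
  samps <- unique(records$sample_id)
  m <- matrix(NA_real_, length(feats), length(samps),
              dimnames = list(feats, samps))
  m[cbind(match(records$feature_id, feats),
          match(records$sample_id, samps))] <- records$ct
  ctl <- tapply(records$is_control, records$feature_id, any)[feats]
  pool <- tapply(records$pool, records$feature_id,
                 function(p) p[1])[feats]
  CtExperiment(m, isControl = as.logical(ctl), pool = unname(pool))
}

.parse_logical <- function(x, what) {
  x <- trimws(tolower(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out))
    stop(sprintf("column %s: unrecognised logical token '%s'",
                 what, x[is.na(out)][1]))
  out
}

## case-table enum vocabularies; spellings follow the published case tables
.CASE_ENUMS <- list(
  sex = c(M = "M", F = "F"),
  location = c(Stomach = "stomach", Jejunum = "jejunum", Ileum = "ileum",
               Retroperitoneum = "retroperitoneum"),
  fish_14q = c(Loss = "loss", Diploid = "diploid", Trisomy = "trisomy",
               `NA` = "not_tested"),
  sdhb_ihc = c(positive = "positive", negative = "negative",
               `NA` = "not_tested"),
  followup = c(DOD = "DOD", WD = "WD", AWD = "AWD", `NA` = "not_available"),
  risk = c(L = "L", I = "I", H = "H", `NA` = "not_available")
)

.map_enum <- function(x, field) {
  vocab <- .CASE_ENUMS[[field]]
  x <- trimws(x)
  unknown <- !x %in% names(vocab)
  if (any(unknown))
    stop(sprintf("case table: unknown %s token '%s'", field, x[unknown][1]))
  unname(vocab[x])
}

#' Read a per-case clinical/genomic metadata table
#'
#' Expects columns `case_id`, `sex`, `age`, `location`, `genotype`,
#' `mutation`, `fish_14q`, `sdhb_ihc`, `followup`, `risk`, `histology`,
#' `carney_triad`, with the spellings used in the published case tables
#' (`DOD`/`WD`/`AWD`, `L`/`I`/`H`, `Loss`/`Diploid`/`Trisomy`, `NA` for
#' untested/unavailable). Genotype tokens such as `"KIT ex 11"` are
#' normalized to the gene symbol; age `< 20` years classifies a case as
#' pediatric. Unknown enum tokens are errors, not guesses.
#'
#' @param path file path.
#' @param delim delimiter; inferred from extension if `NULL`.
#' @return data.frame of validated case records with normalized enums and
#'   a derived `age_class` column (`adult`/`pediatric`).
#' @export
readCaseTable <- function(path, delim = NULL) {
  df <- .read_delim(path, delim)
  if (nrow(df) == 0L) {
    warning("case table is empty: ", path)
    return(data.frame(case_id = character(), age_class = character(),
                      sex = character(), age = numeric(),
                      location = character(), genotype = character(),
                      mutation = character(), fish_14q = character(),
                      sdhb_ihc = character(), carney_triad = logical(),
                      risk = character(), followup = character(),
                      histology = character(), stringsAsFactors = FALSE))
  }
  .require_cols(df, c("case_id", "sex", "age", "location", "genotype",
                      "mutation", "fish_14q", "sdhb_ihc", "followup",
                      "risk", "histology", "carney_triad"), "case table")
  if (anyDuplicated(df$case_id))
    stop("case table: duplicate case_id: ",
         df$case_id[duplicated(df$case_id)][1])
  age <- suppressWarnings(as.numeric(df$age))
  if (anyNA(age)) stop("case table: non-numeric age at data row ",
                       which(is.na(age))[1])
  gene <- sub("^([A-Za-z0-9]+).*$", "\\1", trimws(df$genotype))
  if (!all(gene %in% c("KIT", "PDGFRA", "BRAF", "WT")))
    stop("case table: unknown genotype token '",
         df$genotype[!gene %in% c("KIT", "PDGFRA", "BRAF", "WT")][1], "'")
  mutation <- trimws(df$mutation)
  mutation[mutation %in% c("NA", "")] <- NA_character_
  is_wt_mut <- is.na(mutation) | mutation == "WT"
  if (any((gene == "WT") != is_wt_mut))
    stop("case table: genotype/mutation inconsistency for case ",
         df$case_id[(gene == "WT") != is_wt_mut][1])
  out <- data.frame(
    case_id = trimws(df$case_id),
    age_class = ifelse(age < 20, "pediatric", "adult"),
    sex = .map_enum(df$sex, "sex"),
    age = age,
    location = .map_enum(df$location, "location"),
    genotype = gene,
    mutation = mutation,
    fish_14q = .map_enum(df$fish_14q, "fish_14q"),
    sdhb_ihc = .map_enum(df$sdhb_ihc, "sdhb_ihc"),
    carney_triad = .parse_logical(df$carney_triad, "carney_triad"),
    risk = .map_enum(df$risk, "risk"),
    followup = .map_enum(df$followup, "followup"),
    histology = ifelse(trimws(df$histology) %in% c("NA", ""), NA_character_,
                       trimws(df$histology)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a predicted miRNA-to-gene target pair table
#'
#' @param path 2+ column CSV/TSV with columns `mirna_id`, `gene_id`.
#' @param mirnaUniverse,geneUniverse optional background universes; ids in
#'   the file outside a supplied universe are an error.
#' @param delim delimiter; inferred if `NULL`.
#' @return a [TargetTable-class].
#' @export
readTargetTable <- function(path, mirnaUniverse = NULL, geneUniverse = NULL,
                            delim = NULL) {
  df <- .read_delim(path, delim)
  .require_cols(df, c("mirna_id", "gene_id"), "target table")
  if (is.null(mirnaUniverse)) mirnaUniverse <- unique(df$mirna_id)
  if (is.null(geneUniverse)) geneUniverse <- unique(df$gene_id)
  TargetTable(df, mirnaUniverse = mirnaUniverse, geneUniverse = geneUniverse)
}

#' Read methylation-specific PCR band calls
#'
#' One row per assayed case: presence/absence of the maternal
#' (unmethylated-allele) and paternal (methylated-allele) MEG3-promoter
#' bands, plus a bisulfite-conversion control flag. Records with a failed
#' conversion control are retained but will classify as uninterpretable.
#'
#' @param path CSV/TSV with columns `case_id`, `maternal_band`,
#'   `paternal_band`, `conversion_control_ok`.
#' @param delim delimiter; inferred if `NULL`.
#' @return validated data.frame.
#' @export
readMethylationCalls <- function(path, delim = NULL) {
  df <- .read_delim(path, delim)
  .require_cols(df, c("case_id", "maternal_band", "paternal_band",
                      "conversion_control_ok"), "methylation calls")
  if (anyDuplicated(df$case_id))
    stop("methylation calls: duplicate case_id")
  data.frame(case_id = trimws(df$case_id),
             maternal_band = .parse_logical(df$maternal_band, "maternal_band"),
             paternal_band = .parse_logical(df$paternal_band, "paternal_band"),
             conversion_control_ok =
               .parse_logical(df$conversion_control_ok,
                              "conversion_control_ok"),
             stringsAsFactors = FALSE)
}

#' Write / read back a result table
#'
#' Writes any result data.frame as delimited text with `NA` as the missing
#' sentinel; `readResults()` inverts it, so write-then-read is the identity
#' on valid tables (column classes are restored from the data).
#'
#' @param table a data.frame.
#' @param path output path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeResults <- function(table, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (is.null(table)) stop("table must be non-null")
  utils::write.table(as.data.frame(table), path,
                     sep = if (format == "csv") "," else "\t",
                     row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  utils::read.table(path, header = TRUE,
                    sep = if (format == "csv") "," else "\t",
                    quote = "\"", na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
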