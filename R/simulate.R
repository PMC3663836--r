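## Synthetic-cohort generator. Emulates the statistical structure the
## analysis assumes -- a two-card 667-miRNA Ct profile over three cohort
## classes, a 47-member co-regulated imprinted block whose level tracks a
## per-case 14q32 allelic state, an SDHB-status signature, Ct-dependent
## dropout, methylation band calls, and a predicted-target table with
## enriched diametric pairs -- so every pipeline stage is testable without
## the (undeposited) raw array data. Effects are simulated on the Ct
## scale, where the measurement process (and its dropout) lives.

#' Configuration for the synthetic cohort
#'
#' Defaults mirror the study conditions: class sizes 30/25/18 (adult
#' mutant / adult WT / pediatric WT), 667 miRNAs plus 6 internal-control
#' assays split over card pools A/B, a 47-miRNA imprinted block, a
#' 16-miRNA SDHB signature, and an adult allelic-state mixture of
#' 9 paternal-loss : 5 maternal-loss : 4 normal (the tested proportions).
#' Pediatric cases (and SDHB-negative adult WT cases, which co-cluster
#' with them) default to a normal imprinting pattern with block-low
#' expression driven by an "other mechanism" flag.
#'
#' @param n_adult_mutant,n_adult_wt,n_pediatric class sizes.
#' @param n_features number of miRNA assays (controls are added on top).
#' @param block_size size of the imprinted 14q32 block.
#' @param block_shift_ct Ct shift (positive = lower expression) of block
#'   miRNAs in block-silenced cases, default 4 Ct (16-fold).
#' @param block_ct_mean,block_ct_sd baseline Ct distribution of the block
#'   miRNAs (defaults 26 and 1). The imprinted cluster is one
#'   abundantly expressed polycistronic transcript, so its members sit
#'   below the global baseline; this keeps silenced-state values
#'   detectable (below the censor threshold), as the study's observed
#'   block was by construction.
#' @param sdhb_signature_size,sdhb_shift_ct size and Ct shift of the
#'   SDHB-status signature (half the features shift each way).
#' @param planted_de optional named list: comparison name (one of the
#'   class comparisons 1-5 of [enumerateComparisons()]) -> list with
#'   `n_features` and `shift` (Ct added to group `a`).
#' @param baseline_ct_mean,baseline_ct_sd per-feature baseline Ct level
#'   distribution (defaults 28 and 2).
#' @param noise_sd per-well technical + biological noise sd in Ct
#'   (default 1).
#' @param missingness_center,missingness_slope logistic dropout model:
#'   `P(missing | ct) = plogis(slope * (ct - center))`, defaults 34, 1.5.
#' @param contamination_rate probability that a loss case emits a normal
#'   band pattern (stromal DNA admixture), default 0.15.
#' @param n_genes gene universe size for the target table.
#' @param n_genes_up significant genes per direction per comparison in the
#'   emitted gene DE table.
#' @param target_density_background,target_density_planted probability of
#'   a predicted pair outside / inside the planted diametric sets
#'   (defaults 0.02 and 0.10, a 5x enrichment).
#' @param seed integer seed; identical configs and seeds give
#'   bit-identical outputs.
#' @return validated config list of class `SimConfig`.
#' @export
simConfig <- function(n_adult_mutant = 30, n_adult_wt = 25,
                      n_pediatric = 18, n_features = 667,
                      block_size = 47, block_shift_ct = 4.0,
                      block_ct_mean = 26, block_ct_sd = 1.0,
                      sdhb_signature_size = 16, sdhb_shift_ct = 3.0,
                      planted_de = NULL,
                      baseline_ct_mean = 28, baseline_ct_sd = 2,
                      noise_sd = 1.0,
                      missingness_center = 34, missingness_slope = 1.5,
                      contamination_rate = 0.15,
                      n_genes = 1000, n_genes_up = 50,
                      target_density_background = 0.02,
                      target_density_planted = 0.10,
                      seed = 1L) {
  cfg <- as.list(environment())
  if (block_size < 0 || block_size > n_features)
    stop("simConfig: block_size must be in [0, n_features]")
  if (sdhb_signature_size < 0 ||
      block_size + sdhb_signature_size > n_features)
    stop("simConfig: block + signature exceed n_features")
  if (target_density_background < 0 || target_density_background > 1 ||
      target_density_planted < 0 || target_density_planted > 1)
    stop("simConfig: target densities must be in [0, 1]")
  if (any(c(n_adult_mutant, n_adult_wt, n_pediatric) < 2))
    stop("simConfig: class sizes must be >= 2")
  structure(cfg, class = "SimConfig")
}

## deterministic sub-seed per table so adding a table does not perturb
## earlier draws; kept below 2^31
.sub_seed <- function(seed, k) (as.integer(seed) %% 1000003L) * 1009L + k

#' Simulate a complete synthetic study cohort
#'
#' Draws the full input bundle for the pipeline: a raw
#' [CtExperiment-class] (some values above the censor threshold, dropout
#' by the logistic missingness model), a case metadata table, methylation
#' band calls consistent with the per-case allelic state up to a
#' contamination rate, a gene DE table for the diametric comparisons, a
#' predicted-target [TargetTable-class] with planted enrichment, and the
#' generating truth.
#'
#' Block miRNAs are shifted by `block_shift_ct` in cases whose 14q32 state
#' silences the cluster (maternal-allele loss, or the pediatric-type
#' "other mechanism"); the expressing paternal-loss and normal-pattern
#' cases are unshifted. SDHB-negative cases carry the signature shift.
#'
#' @param cfg a [simConfig()] object.
#' @return list with elements `ct`, `cases`, `meth_calls`, `gene_de`,
#'   `targets`, `truth`.
#' @export
simulateCohort <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "SimConfig"))
  n <- cfg$n_adult_mutant + cfg$n_adult_wt + cfg$n_pediatric
  case_id <- c(sprintf("AM%02d", seq_len(cfg$n_adult_mutant)),
               sprintf("AW%02d", seq_len(cfg$n_adult_wt)),
               sprintf("PW%02d", seq_len(cfg$n_pediatric)))
  cls <- rep(c("adult_mutant", "adult_wt", "pediatric_wt"),
             c(cfg$n_adult_mutant, cfg$n_adult_wt, cfg$n_pediatric))

  ## --- case metadata, SDHB status, allelic state -------------------------
  cases_and_truth <- .with_seed(.sub_seed(cfg$seed, 1L), {
    ## genotypes for adult mutants at the cohort's exact 18:11:1
    ## proportions, shuffled
    n_am <- cfg$n_adult_mutant
    n_geno <- diff(round(cumsum(c(0, 18, 11, 1)) / 30 * n_am))
    geno <- rep("WT", n)
    geno[cls == "adult_mutant"] <-
      sample(rep(c("KIT", "PDGFRA", "BRAF"), n_geno))
    ## SDHB: mutants positive; adult WT negative at the tested 11:7
    ## proportions; pediatric negative
    n_aw <- cfg$n_adult_wt
    n_neg <- round(n_aw * 11 / 18)
    sdhb <- rep("positive", n)
    sdhb[cls == "pediatric_wt"] <- "negative"
    sdhb[cls == "adult_wt"] <-
      sample(rep(c("negative", "positive"), c(n_neg, n_aw - n_neg)))
    ## allelic state: adult mutant and SDHB+ adult WT carry the tested
    ## 9:5:4 paternal-loss : maternal-loss : normal mixture at exact
    ## scaled counts (shuffled); pediatric and SDHB- adult WT keep the
    ## normal pattern and silence the block by the "other mechanism"
    mixture_case <- cls == "adult_mutant" |
      (cls == "adult_wt" & sdhb == "positive")
    allelic <- rep("normal_pattern", n)
    for (grp in list(which(cls == "adult_mutant"),
                     which(cls == "adult_wt" & sdhb == "positive"))) {
      k <- length(grp)
      n_pat <- round(9 / 18 * k)
      n_mat <- round(5 / 18 * k)
      allelic[grp] <- sample(rep(c("paternal_loss", "maternal_loss",
                                   "normal_pattern"),
                                 c(n_pat, n_mat, k - n_pat - n_mat)))
    }
    other_mechanism <- !mixture_case
    age <- ifelse(cls == "pediatric_wt", sample(8:19, n, replace = TRUE),
                  sample(20:85, n, replace = TRUE))
    fish <- ifelse(allelic %in% c("paternal_loss", "maternal_loss"),
                   "loss", "diploid")
    list(cases = data.frame(
           case_id = case_id,
           age_class = ifelse(cls == "pediatric_wt", "pediatric", "adult"),
           sex = sample(c("F", "M"), n, replace = TRUE, prob = c(2, 1)),
           age = age,
           location = "stomach",
           genotype = geno,
           mutation = ifelse(geno == "WT", NA_character_, "simulated"),
           fish_14q = fish,
           sdhb_ihc = sdhb,
           carney_triad = FALSE,
           risk = sample(c("L", "I", "H"), n, replace = TRUE),
           followup = ifelse(cls == "adult_mutant",
                             sample(c("WD", "AWD", "DOD"), n, replace = TRUE,
                                    prob = c(.6, .25, .15)),
                             "not_available"),
           histology = "E",
           stringsAsFactors = FALSE),
         allelic = stats::setNames(allelic, case_id),
         other_mechanism = stats::setNames(other_mechanism, case_id))
  })
  cases <- cases_and_truth$cases
  allelic <- cases_and_truth$allelic
  other <- cases_and_truth$other_mechanism

  ## --- feature roster ----------------------------------------------------
  feat <- sprintf("miR-sim-%04d", seq_len(cfg$n_features))
  controls <- c("MammU6", "RNU24", "RNU43", "RNU44", "RNU48", "RNU6B")
  block <- feat[seq_len(cfg$block_size)]
  sig <- feat[cfg$block_size + seq_len(cfg$sdhb_signature_size)]
  sig_up_in_neg <- sig[seq_len(floor(length(sig) / 2))]
  sig_down_in_neg <- setdiff(sig, sig_up_in_neg)

  ## --- Ct matrix ---------------------------------------------------------
  ct_data <- .with_seed(.sub_seed(cfg$seed, 2L), {
    baseline <- stats::rnorm(cfg$n_features, cfg$baseline_ct_mean,
                             cfg$baseline_ct_sd)
    ## block members form one abundantly expressed polycistron
    baseline[feat %in% block] <- stats::rnorm(length(block),
                                              cfg$block_ct_mean,
                                              cfg$block_ct_sd)
    m <- matrix(stats::rnorm(cfg$n_features * n, 0, cfg$noise_sd),
                cfg$n_features, n, dimnames = list(feat, case_id)) + baseline
    silenced <- allelic[case_id] == "maternal_loss" | other[case_id]
    m[block, silenced] <- m[block, silenced] + cfg$block_shift_ct
    sdhb_neg <- cases$sdhb_ihc == "negative"
    m[sig_up_in_neg, sdhb_neg] <- m[sig_up_in_neg, sdhb_neg] -
      cfg$sdhb_shift_ct
    m[sig_down_in_neg, sdhb_neg] <- m[sig_down_in_neg, sdhb_neg] +
      cfg$sdhb_shift_ct
    planted <- list()
    if (!is.null(cfg$planted_de)) {
      free <- setdiff(feat, c(block, sig))
      specs <- enumerateComparisons(cases, verbose = FALSE)
      for (nm in names(cfg$planted_de)) {
        pd <- cfg$planted_de[[nm]]
        sp <- Filter(function(s) s$name == nm, specs)
        if (!length(sp))
          stop("simulateCohort: planted_de comparison not available: ", nm)
        take <- free[seq_len(pd$n_features)]
        free <- setdiff(free, take)
        m[take, sp[[1]]$a] <- m[take, sp[[1]]$a] + pd$shift
        planted[[nm]] <- take
      }
    }
    ## logistic dropout on the true Ct, then controls appended
    p_miss <- stats::plogis(cfg$missingness_slope *
                              (m - cfg$missingness_center))
    m[stats::runif(length(m)) < p_miss] <- NA_real_
    ctl <- matrix(stats::rnorm(length(controls) * n, 20, 0.5),
                  length(controls), n,
                  dimnames = list(controls, case_id))
    list(m = rbind(m, ctl), planted = planted,
         expected_missing = mean(p_miss))
  })
  all_feat <- rownames(ct_data$m)
  ct <- CtExperiment(ct_data$m,
                     isControl = all_feat %in% controls,
                     pool = rep(c("A", "B"), length.out = length(all_feat)),
                     colData = DataFrame(cases, row.names = cases$case_id))

  ## --- methylation band calls -------------------------------------------
  meth <- .with_seed(.sub_seed(cfg$seed, 3L), {
    contaminated <- stats::runif(n) < cfg$contamination_rate
    st <- ifelse(allelic[case_id] != "normal_pattern" & contaminated,
                 "normal_pattern", allelic[case_id])
    data.frame(case_id = case_id,
               maternal_band = st %in% c("normal_pattern", "paternal_loss"),
               paternal_band = st %in% c("normal_pattern", "maternal_loss"),
               conversion_control_ok = TRUE,
               stringsAsFactors = FALSE)
  })

  ## --- gene DE table and predicted-target pairs --------------------------
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  tg <- .with_seed(.sub_seed(cfg$seed, 4L), {
    comps <- c("adult_mutant_vs_pediatric", "adult_vs_pediatric",
               "wt_vs_mutant", "adult_wt_vs_pediatric_wt")
    gene_de <- do.call(rbind, lapply(comps, function(cmp) {
      pick <- sample(genes, 2 * cfg$n_genes_up)
      data.frame(comparison = cmp,
                 gene_id = pick,
                 direction = rep(c("higher_in_a", "higher_in_b"),
                                 each = cfg$n_genes_up),
                 significant = TRUE, stringsAsFactors = FALSE)
    }))
    ## planted enrichment: block miRNAs (lower in pediatric than adult
    ## mutant) x genes up in pediatric, at the planted density
    genes_up_ped <- gene_de$gene_id[
      gene_de$comparison == "adult_mutant_vs_pediatric" &
      gene_de$direction == "higher_in_b"]
    dens <- matrix(cfg$target_density_background, cfg$n_features,
                   cfg$n_genes, dimnames = list(feat, genes))
    dens[block, genes_up_ped] <- cfg$target_density_planted
    hit <- which(matrix(stats::runif(length(dens)), nrow(dens)) < dens,
                 arr.ind = TRUE)
    pairs <- data.frame(mirna_id = feat[hit[, 1]],
                        gene_id = genes[hit[, 2]],
                        stringsAsFactors = FALSE)
    list(gene_de = gene_de, pairs = pairs, genes_up_ped = genes_up_ped)
  })
  targets <- TargetTable(tg$pairs, mirnaUniverse = feat,
                         geneUniverse = genes)

  list(ct = ct, cases = cases, meth_calls = meth, gene_de = tg$gene_de,
       targets = targets,
       truth = list(block = block,
                    sdhb_signature = sig,
                    sdhb_signature_up_in_negative = sig_up_in_neg,
                    allelic_state = allelic,
                    other_mechanism = other,
                    planted_de = ct_data$planted,
                    genes_up_pediatric = tg$genes_up_ped,
                    expected_missing_fraction = ct_data$expected_missing))
}

#' Write a simulated cohort as plain tables
#'
#' Emits the Ct matrix (long format), case table, methylation calls, gene
#' DE table and target pairs of a [simulateCohort()] result as TSV files.
#'
#' @param sim result of [simulateCohort()].
#' @param outdir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
writeCohortTables <- function(sim, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("writeCohortTables: cannot create directory: ", outdir)
  ctm <- assay(sim$ct, "ct")
  long <- data.frame(
    feature_id = rep(rownames(ctm), ncol(ctm)),
    sample_id = rep(colnames(ctm), each = nrow(ctm)),
    ct = as.vector(ctm),
    pool = rep(rowData(sim$ct)$pool, ncol(ctm)),
    is_control = rep(rowData(sim$ct)$is_control, ncol(ctm)),
    stringsAsFactors = FALSE)
  long <- long[!is.na(long$ct), ]
  paths <- file.path(outdir, c("ct_long.tsv", "cases.tsv",
                               "meth_calls.tsv", "gene_de.tsv",
                               "target_pairs.tsv"))
  writeResults(long, paths[1], "tsv")
  writeResults(sim$cases, paths[2], "tsv")
  writeResults(sim$meth_calls, paths[3], "tsv")
  writeResults(sim$gene_de, paths[4], "tsv")
  writeResults(targetPairs(sim$targets), paths[5], "tsv")
  invisible(paths)
}
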