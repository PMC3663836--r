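---
title: "miRNA profiling of GIST subtypes: models, parameters and design notes"
author: "mirgist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miRNA profiling of GIST subtypes: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirgist)
```

# The scientific setting

Gastrointestinal stromal tumors (GIST) split into adult cases driven by
activating *KIT*/*PDGFRA*/*BRAF* mutations and a "wild-type" group —
including essentially all pediatric cases — that lacks them and is
typically SDHB-immunonegative. miRNA profiling of such cohorts on TaqMan
low-density arrays (two 384-well cards, pools A and B, 667 miRNAs plus
MammU6/RNU internal controls) shows that the dominant structure in the
expression matrix is a block of 47 co-regulated miRNAs from the imprinted
14q32 (DLK1–DIO3) locus. These miRNAs are transcribed as one
polycistronic unit from the maternal allele only; the paternal allele is
silenced by methylation of the MEG3-promoter DMR. Consequently:

* loss of the **paternal** allele is expressionally **silent** — FISH
  sees a 14q32 deletion but the block stays expressed;
* loss of the **maternal** allele abolishes block expression even though
  the FISH picture is the same.

This package implements the complete analysis around that observation:
Ct pre-processing, Spearman/Ward clustering with block removal and
re-clustering, rank-sum differential expression over the cohort's class
comparisons, over-representation of predicted miRNA:mRNA interactions
among diametrically expressed sets, and interpretation of
methylation-specific PCR band calls into per-case allelic states with
cluster-wise concordance summaries. Because the raw array data are not
publicly deposited, a synthetic-cohort generator reproduces the
statistical structure the analysis assumes, making every stage testable.

# Pre-processing model

Raw Ct values pass through a fixed four-stage chain, enforced through the
`stage` slot of `CtExperiment`:

1. **Censoring** — Ct values strictly above 35 are amplification noise
   and become missing. The comparison is strict (`> 35`), so 35 itself
   survives; censoring is idempotent.
2. **Detection filtering** — a miRNA is kept iff detected in at least
   20% of samples (`>=`, so exactly 20% survives); internal controls are
   removed unconditionally. The denominator is the number of samples in
   the matrix (no sample-level exclusions are defined).
3. **Mean normalization** — each present Ct has its sample's mean
   present Ct subtracted, so every sample's mean normalized Ct is zero
   (tolerance 1e-9). The controls do not contribute to the mean, since
   normalization is by the sample mean rather than by endogenous
   controls.
4. **Relative expression** — `expression = 2^(Ctmax − Ct)` where `Ctmax`
   is the maximum present normalized Ct. The default scope is *global*
   (one reference for the whole matrix): the singular reference yields
   the invariants "every present value ≥ 1" and "minimum = 1 at the
   Ctmax cell". A per-feature scope (each row uses its own maximum) is
   available via `ctMaxScope = "feature"`. `Ctmax` is computed *after*
   mean normalization, since the transform is applied to normalized
   values; this choice only shifts the expression scale and leaves all
   rank-based downstream statistics untouched.

Pools A and B are concatenated into one per-sample profile before
normalization; the two cards are treated as one 667-miRNA measurement.

All floating-point comparisons in the package use an absolute tolerance
of 1e-9.

# Clustering

Sample dissimilarity is `1 − ρ` with Spearman's rank correlation over
the features present in both samples (average ranks on ties), giving
values in `[0, 2]`. Pairwise-complete computation is guarded by a
minimum overlap of 10 shared features — silent NA propagation would
poison the tree. Because the measure is rank-based, it is invariant to
any strictly monotone transform of a sample's values, so Ct-scale and
expression-scale inputs yield identical trees.

Agglomeration uses Ward's minimum-variance criterion via
`stats::hclust(method = "ward.D")`, i.e. the Lance–Williams update on
the dissimilarities *as given*. The squared-dissimilarity dialect
(`ward.D2`) is exposed through `wardHclust(..., squared = TRUE)`; the
plain dialect is the default because it matches the default behaviour of
the statistical environments of the era this analysis style comes from.
The test suite cross-checks the agglomeration against an independent
brute-force Lance–Williams implementation on small instances.

Heatmap colouring uses within-feature ranks across samples
(`rankHeatmapMatrix()`), which makes the display invariant to the Ctmax
convention.

**Cluster naming** (A/B, B1/B2, B2a/B2b) is a presentation layer over
recursive `k = 2` cuts. The published semantics cannot be recovered from
cut heights alone, so `nestedClusterLabels()` orients the naming when a
feature block is supplied: A is the top cluster with higher mean rank
expression of the block (the 14q32-expressing cluster), B1 is the
smaller B subcluster (the silenced adult-mutant group), B2a the larger
B2 subcluster; remaining ties break on the smallest member id, which
also makes the labelling deterministic. `runPipeline()` orients with the
computed split drivers.

# Differential expression

Each of the ten class comparisons (adult mutant vs pediatric, adult WT
vs pediatric WT, all adult vs pediatric, adult WT vs adult mutant, WT vs
mutant, B2a vs B2b, SDHB+ vs SDHB−, 14q32 loss vs no loss, high vs low
risk, DOD/AWD vs no evidence of disease) is tested feature-wise with the
two-sided Wilcoxon rank-sum test. In `auto` mode the exact null
distribution is enumerated when the smaller group has ≤ 8 observations
and the pooled values are tie-free; otherwise the normal approximation
with tie-variance and continuity corrections applies.

Multiplicity control is Bonferroni with the family defined as the
features actually tested *within* each comparison — features need at
least two present values per group; those failing the rule are dropped
from the family (and logged). The family is per-comparison rather than
global because the eligible feature sets differ between comparisons and
the published result tables are organised per comparison. Significance
is called on the adjusted p-value (`p_adj = min(1, m·p) < α`); an
`correct = FALSE` escape hatch calls raw p-values instead, since the
published wording ("p < 0.05 … corrected") is ambiguous. Comparisons
with an empty group on a given case table are skipped with a logged
reason, not an error.

# Diametric target integration

For a class contrast, the *diametric* sets are the significant miRNAs
moving one way and the significant genes moving the other
(`diametricSchemes()` encodes the five distinct published pairings; the
published list states the pediatric-vs-adult-mutant pairing twice and it
is encoded once). The observed statistic is the number of predicted
miRNA→gene pairs (TargetScan-style, taken at face value per miRNA id)
connecting the two sets.

The original custom software's null is unspecified, so two explicit
nulls bracket it:

* **Permutation (default)** — gene sets of equal size are resampled
  uniformly without replacement from the gene universe with the miRNA
  set fixed; `p = (1 + #(null ≥ obs)) / (1 + n_perm)`. This conditions
  on the miRNA set's target degrees (degree-aware). A flag permutes the
  miRNA side instead.
* **Hypergeometric** — pair membership treated as hypergeometric in the
  flattened pair space (miRNA set × gene universe); degree-blind but
  closed-form. Both nulls share the expectation
  `|genes_up| / |universe| · Σ_m deg(m)`.

Background universes are the measured-and-expressed miRNAs/genes
(post-filter), not the genome — standard over-representation practice
that avoids detection-bias inflation. With a fixed seed the permutation
result is bit-identical across runs. The published interaction p-values
depend on unpublished gene-expression data and are not reproduction
targets.

# 14q32 allelic state and concordance

Methylation-specific PCR of the MEG3-promoter DMR yields a maternal
(unmethylated-allele) and a paternal (methylated-allele) band.
`classifyAllelicState()` is total over the 2×2×2 band/control space:
both bands → normal imprinted pattern; maternal only → paternal loss
(silent); paternal only → maternal loss; no bands or failed bisulfite
conversion → uninterpretable. "Normal pattern despite FISH loss" is
reported as a discordance — attributed in practice to stromal DNA
admixture — and never silently reclassified. Concordance fractions are
kept at full precision with a rounded integer-percent display column,
matching the convention of the reported 82%/75%/83% figures.

The per-case band calls behind the published cluster concordances are
not available; `clusterMethylationCalls()` reconstructs a call table
from the reported aggregate outcomes (9/12 paternal loss in cluster A,
5/6 maternal loss in B1) with synthetic placeholder case ids, which is
sufficient for every count-level summary.

# The synthetic cohort

`simulateCohort()` draws the full input bundle. Its defaults *are* the
study conditions; where the study reports no value, a choice was made
once on field conventions and is listed here:

| parameter | default | basis |
|---|---|---|
| class sizes | 30 / 25 / 18 | reported cohort composition |
| features | 667 (+6 controls) | two-card TLDA panel |
| block size / shift | 47 / 4 Ct | reported block; strong (16-fold) silencing |
| block baseline | N(26, 1) | abundantly expressed polycistron (see below) |
| SDHB signature | 16 features, ±3 Ct | reported signature size; half up, half down |
| baseline Ct | N(28, 2) per feature | conventional TLDA range |
| per-well noise | sd 1 Ct | FFPE technical + biological variation |
| dropout | logistic, centre 34, slope 1.5 | detection failure near the censor zone |
| allelic mixture | 9 : 5 : 4 scaled, exact counts | reported tested proportions |
| methylation contamination | 0.15 | stromal admixture producing normal bands |
| target densities | 0.02 background, 0.10 planted | 5× planted enrichment |

Effects are simulated on the Ct scale, where the measurement process and
its dropout live; expression-scale effects follow from the `2^` transform.
Block miRNAs are silenced (+4 Ct) in maternal-loss cases and in
"other mechanism" cases (all pediatric and SDHB-negative adult WT, whose
block is low despite normal imprinting); paternal-loss and
normal-pattern cases express the block. Class composition (genotypes,
SDHB status, allelic states) uses exact scaled proportions rather than
multinomial draws, so every replicate has the study's composition.

Two generator choices deserve justification. *Block baselines* come from
N(26, 1) rather than the global N(28, 2): the 14q32 miRNAs derive from
one abundantly expressed polycistronic transcript, and — more to the
point — the 47 block members the study reports are by construction
miRNAs that remained detectable on both sides of the split; drawing
block baselines from the global distribution would place some silenced
values above the censor threshold and make them untestable, which
contradicts their presence on the reported list. *Exact-count class
composition* avoids degenerate replicates (e.g. too few maternal-loss
adult mutants for the exact rank-sum test to reach Bonferroni
significance at all).

One global seed drives deterministic per-table sub-seeds, so adding a
table to the bundle does not perturb earlier draws; identical configs
and seeds give bit-identical outputs.

**What the generator does not emulate.** Real miRNA sequence content and
genomic coordinates; inter-card batch effects; amplification-efficiency
differences; correlated co-expression outside the planted structures;
heavy-tailed FFPE degradation noise. Passing tests therefore demonstrate
correctness of the *procedures* under the assumed data-generating
process, not performance guarantees on arbitrary clinical material.

# Known limitations

* **Mean-normalization leakage.** Silencing 47 of 667 features by 4 Ct
  shifts the silenced samples' mean by 4 × 47/667 ≈ 0.28 Ct, which mean
  normalization redistributes into *every other* feature as a small
  systematic between-group shift. In driver identification this inflates
  the false-positive rate slightly above the Bonferroni budget; in our
  replicate studies the planted block is recovered exactly (47/47, no
  extras) in roughly 60–75% of runs, with the remainder off by one or
  two features in either direction. This is a property of the published
  normalization itself whenever one dominant block moves, not of the
  implementation.
* **Boundary interactions.** Features whose silenced-state values
  approach the Ct-35 censor lose observations asymmetrically; survivor
  selection then biases the remaining values toward the detectable side
  and compresses rank separation.
* The B2a/B2b contrast depends on a clustering labelling and is only as
  stable as the underlying cut; no bootstrap/consensus stability
  assessment is implemented because none was part of the original
  analysis.

# Problem sizes used by the test suite

The suite exercises full-size cohorts (667 features × 73 samples) for
structural checks, 50 replicates for the block-recovery study, 300–500
null families for family-wise error calibration, and exhaustive
enumeration oracles on instances small enough to enumerate (rank-sum
n ≤ 12, 5-gene enrichment universes, ≤ 6-point dendrograms) — sizes
chosen so each oracle is literally exhaustive while the Monte-Carlo
components keep tight binomial margins.

# A worked run

```{r pipeline, eval = FALSE}
sim <- simulateCohort(simConfig(seed = 1))
res <- runPipeline(sim$ct, sim$cases, methCalls = sim$meth_calls,
                   geneDe = sim$gene_de, targets = sim$targets,
                   nPermutations = 10000, seed = 1)
table(res$labels$nested)   # A / B1 / B2a / B2b sizes
length(res$split_drivers)  # features driving the top split
res$enrichment             # diametric interaction over-representation
res$concordance            # allelic-state concordance by cluster
```

The pipeline log records censor/filter counts, Bonferroni family sizes
and the enrichment null type — the quantities needed to audit a run.
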