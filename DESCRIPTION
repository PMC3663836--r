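Package: mirgist
Title: miRNA Profiling Analysis of Gastrointestinal Stromal Tumor Subtypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for TaqMan low-density-array miRNA profiling
    of gastrointestinal stromal tumor (GIST) cohorts. Implements Ct
    pre-processing (noise censoring, detection filtering, per-sample mean
    normalization, conversion to relative expression), unsupervised
    hierarchical clustering with Spearman rank dissimilarity and Ward
    linkage, Wilcoxon rank-sum differential expression with Bonferroni
    control over the canonical GIST class comparisons, over-representation
    testing of predicted miRNA:mRNA interactions among diametrically
    expressed sets, and classification of 14q32 (DLK1-DIO3) allelic state
    from methylation-specific PCR band calls and FISH copy state. A
    synthetic-cohort generator with planted structure supports end-to-end
    testing without access to raw array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
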