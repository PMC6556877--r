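Package: adipodecon
Title: Cell-Type Deconvolution of Bulk Adipose RNA-Seq and Downstream
    Cell-Aware Genetic Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the relative proportions of four cell types
    (adipocytes, macrophages, microvascular endothelial cells and CD4+
    T cells) in bulk subcutaneous adipose-tissue RNA-seq profiles by
    nu-support-vector regression against a condition-number-optimised
    signature matrix, and propagates those estimates through the
    analyses that depend on them: in silico mixture benchmarking with
    noise and contaminant spiking, phenotype association, ACE twin
    heritability, and genotype-by-cell-proportion interaction eQTL
    mapping with eigenMT effective-test correction. A synthetic-data
    module emulates the statistical structure of population adipose
    cohorts (replicated reference profiles, Dirichlet mixture
    proportions, MZ/DZ twin pairs, Hardy-Weinberg genotypes) so that
    every stage runs and is testable without access to controlled
    human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    e1071,
    edgeR,
    pracma,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
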