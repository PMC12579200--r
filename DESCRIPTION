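Package: triodnv
Title: Trio-Based De Novo SNV Discovery, Burden and Clinical Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for de novo single-nucleotide-variant (dnSNV)
    analysis in parent-child trio cohorts from whole-exome sequencing calls.
    Covers cohort quality control (genotype-level thresholds, blacklist
    removal, sex imputation, KING-robust kinship, reference-projected
    ancestry PCA), a Mendelian-violation candidate filter cascade with
    programmatic read-support checks replacing visual inspection, de novo
    mutation-rate and class-wise Poisson burden statistics driven by a
    trinucleotide-context mutational model, gene-overlap and hypergeometric
    gene-set enrichment with Benjamini-Hochberg correction, and a regression
    harness (linear and logistic) with diagnostics and post hoc
    minimal-detectable-effect power analysis. Includes a synthetic
    trio-cohort generator with known ground truth (spiked de novo variants,
    inherited variation, and missed-heterozygote artifacts) so the whole
    pipeline is testable without access to protected sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer,
    Biostrings,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
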