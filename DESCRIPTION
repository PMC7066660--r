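Package: splicewise
Title: Information-Theory Prediction and Expression Validation of
    Allele-Specific Alternative mRNA Splicing
Version: 0.1.0
Authors@R:
    person("Splicewise", "Developers", email = "splicewise@example.org",
           role = c("aut", "cre"))
Description: Predicts the impact of single-nucleotide variants on mRNA
    splicing using individual information theory (position weight matrices
    in bits), and validates predictions against three kinds of expression
    evidence: exon-microarray splicing indices with a genotype-stepwise
    filter, replicate qPCR quantification cycles with a
    randomization-based relative-expression test, and spliced-read
    junction evidence classified into exon skipping, cryptic splice site
    use and intron retention.  Includes a synthetic-data generator that
    emulates a genotyped cohort with dose-dependent splicing so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
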