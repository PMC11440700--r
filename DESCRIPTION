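Package: svherd
Title: Structural Variant Call-Set Evaluation for Cattle Cohorts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-calling analysis of structural variant (SV) call sets from
    short-read cohort sequencing: caller-recommended site filtering (MSHQ and
    duphold-style DHFFC thresholds, size and contig rules, GATK hard filters),
    sample sex inference from X and Y to autosome depth ratios, two-caller
    shared-SV identification by reciprocal overlap and genotype concordance,
    SV genotype evaluation via KING-robust kinship against a SNP baseline with
    resampling, SNP-chip overlap and dosage-r2 tag-SNP discovery, gene
    exon/CDS overlap with processed-pseudogene artifact flagging, exact
    Hardy-Weinberg testing and per-SV report cards, plus a fully specified
    synthetic pedigree cohort generator used to exercise the pipeline
    end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
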