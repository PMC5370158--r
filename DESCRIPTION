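Package: codoncooc
Title: Codon-Level Co-Occurrence of Germline and Somatic Variants in Tumors
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects codon-level co-occurrences between germline SNVs and
    somatic mutations in tumor exomes, phases them into cis or trans from
    read evidence, and re-annotates the amino-acid substitution actually
    present in the tumor by applying germline and somatic alleles jointly
    to the reference codon. Provides impact scoring (heuristic silent/stopgain
    scores with a rescaled Grantham surrogate for missense changes, or an
    external score table), codon-substitution enumeration, selection null
    models (genotype-composition cis:trans expectation, codon-position pair
    expectation, MAF resampling null), cohort-level hypothesis tests, and a
    synthetic cohort simulator with planted ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: VariantAnnotation, SomaticMutation, Genetics, Sequencing
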