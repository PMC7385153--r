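Package: hrdpipe
Title: Homologous Recombination Deficiency Identification from Mutational
    Signatures, Genomic Scars and Germline Variant Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for identifying homologous recombination
    deficient (HRD, "BRCAness") tumors in breast-cancer-like cohorts.
    Builds COSMIC-ordered 96-trinucleotide mutation catalogs from somatic
    variant tables, extracts de novo mutational signatures by consensus
    non-negative matrix factorization with singleton-signature handling,
    refits sample exposures against a reference signature set by
    non-negative least squares, computes genomic-scar HRD components
    (LOH, TAI, LST) and the recombination proficiency score, applies a
    germline truncating-variant filter cascade over a DNA damage response
    gene panel, calls promoter-hypermethylation-driven epigenetic
    silencing, and provides the group-comparison statistics (rank-sum
    tests, BH-FDR differential expression, IFN-gamma signature score,
    Tukey outlier handling, ROC cutoff selection) used to classify and
    characterize HRD tumors. Includes a synthetic cohort generator with a
    ground-truth ledger so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tools,
    pracma,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
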