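Package: cordphage
Title: Phage Sequence Detection and Maternal-Infant Sharing Analysis in
    Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies bacteriophage sequences in human-depleted cell-free
    DNA alignment data and quantifies phage-sequence sharing across
    maternal-infant dyads. Parses tabular (outfmt-6 style) alignment hit
    tables against phage sequence databases, resolves multimapping reads to
    a single phage per database by an iterative greedy procedure, calls
    phage presence per sample from unique-read counts and breadth of
    genome coverage, filters ubiquitous (putatively contaminant) phages by
    prevalence, and tests whether phages found in exactly two samples fall
    on maternal-infant dyads more often than expected under a uniform
    random-pair null. Includes a fully synthetic cohort simulator with a
    ground-truth manifest so the entire pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Metagenomics, Sequencing, Coverage, Microbiome
RoxygenNote: 7.3.3
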