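Package: mosaicbe
Title: Base-Editing Outcome Quantification and Off-Target Assessment in
    Mosaic Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Allele-level quantification of cytosine-base-editor outcomes
    from single-blastomere amplicon reads, ploidy-aware mosaic genotyping
    with APOE epsilon-haplotype accounting, transcriptome SNV off-target
    statistics, three-caller trio de novo variant identification, and a
    mismatch-limited protospacer off-target site scanner, driven end to
    end by a synthetic mosaic-embryo data generator with ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
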