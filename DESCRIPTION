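Package: bimodalTF
Title: Dissecting Bimodal Transcription Factor-DNA Binding Specificity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting transcription-factor DNA binding specificity
    into local GC-content, k-mer, and short-tandem-repeat contributions.
    Implements a peak-over-background statistical k-mer binding-energy model
    with ROC/AUC evaluation and a GC-stratified specificity statistic,
    GC-composition-preserving pair-correlation functions with a shuffled null
    and subgroup error bars, TSS-aligned GC/intensity/methylation metaprofiles,
    and a mass-action equilibrium model of competitive bivalent Myc-Max versus
    Smad1 homodimer DNA binding. A synthetic-data module generates genomes,
    peaks, methylation tracks, and expression tables with the statistical
    structure the analysis assumes, so the whole pipeline runs without
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
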