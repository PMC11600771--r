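Package: ampliSNV
Title: Insertion-Capture Variant Calling for Rapid Amplicon Nanopore Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-read hotspot SNV genotyping for multiplex amplicon nanopore
    sequencing panels using modified reference targets: the variant base is
    deleted from each amplicon reference so that every spanning read reports
    its allele as an artificial insertion at the deletion junction, which is
    classified as wild-type, a named mutant, or unrecognizable. Includes a
    seeded multiplex read simulator with a configurable substitution,
    insertion and deletion error model, an affine-gap local aligner with PAF
    import and export, streaming variant-allele-fraction trajectories,
    Welch t-test read-count thresholds between replicate groups, and
    detection-limit experiments, together with a command-line interface and
    a watch mode for incrementally arriving reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
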