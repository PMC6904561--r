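Package: m6ace
Title: Single-Base m6A/m6Am Site Calling and Quantification from
    Exonuclease-Protected Read Starts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for antibody-crosslink/exonuclease RNA
    methylation sequencing (m6ACE-seq). Collates UMI-deduplicated,
    strand-aware read-start counts from aligned fragments; identifies
    m6A/m6Am sites at single-base resolution by negative-binomial
    enrichment of m6ACE over input libraries with shadow-site and
    clustered-noise filtering; quantifies per-site relative methylation
    levels (RML) against a methylated spike-in control; calls
    differential methylation between conditions; and provides metagene,
    TSS-alignment, set-overlap, ROC and consensus-context summaries.
    Includes a generative simulator of m6ACE and input libraries with
    known ground-truth methylomes for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    withr,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Rsamtools
Config/testthat/edition: 3
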