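Package: telomereprofiler
Title: Telomere Content and Variant Repeat Profiling from Aligned Short Reads
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates telomere content from aligned short-read sequencing
    data (BAM) of single samples or matched tumor/control pairs. Telomeric
    reads are extracted by a read-length-scaled hexamer repeat threshold,
    classified into intratelomeric, junction-spanning, subtelomeric and
    intrachromosomal fractions using cytogenetic band annotations, and
    normalized to telomeric reads per GC-content-matched million reads
    (TRPM). Telomere variant repeats (TVRs) are quantified in arbitrary and
    singleton context with base-quality filtering, including per-repeat
    tumor/control log2 ratios and 18-bp sequence context tables. A
    synthetic-fixture generator emits BAM and band files with exact planted
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Rsamtools,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
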