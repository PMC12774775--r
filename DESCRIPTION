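Package: raregrammar
Title: Gapped-Repeat Response Element Grammar in Nuclear Receptor Binding Peaks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the regulatory grammar of nuclear-receptor response
    elements in binding peaks: construction of gapped direct, everted and
    inverted repeats from a half-site position frequency matrix, log-odds
    scanning with a fractional-maximum hit threshold, ZOOPS motif enrichment
    (binomial, Fisher, rank-sum) against first-order Markov or GC-matched
    backgrounds, spacing co-occurrence analysis between a primary half-site
    and secondary motifs, integration of peaks with transcriptome response
    classes by TSS proximity tier, spike-in scalar normalization, and
    promoter chromatin-state transition calls. Includes a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
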