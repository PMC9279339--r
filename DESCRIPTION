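Package: surroseq
Title: Targeted CRISPR-Cas9 Off-Target Evaluation with Barcoded Surrogate Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, quantification and statistical analysis tools for pooled
    barcoded surrogate off-target reporter libraries. Enumerates candidate
    off-target sites for SpCas9 guides against a genome, assembles 170-nt
    Golden-Gate-ready oligos with construct barcodes, processes paired-end
    amplicon sequencing reads from edited and mock samples into per-site
    indel counts via structural, pseudo-edit and positional filtering, calls
    sites with significantly detectable indels by paired Fisher exact testing
    with Benjamini-Hochberg correction, analyses mismatch position and type
    determinants of off-target activity, annotates sites against gene models,
    and simulates fully ground-truthed synthetic inputs for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
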