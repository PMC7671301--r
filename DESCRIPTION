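Package: snoforge
Title: Discovery and Annotation of snoRNAs from Size-Fractionated ncRNA
    Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A verifiable re-implementation of a transcriptomic snoRNA
    discovery workflow for compact eukaryotic genomes. Simulates
    size-fractionated noncoding RNA sequencing libraries (medium-size
    ncRNA with and without 5' cap removal, plus a small RNA fraction)
    with planted C/D box and H/ACA box snoRNAs; calls candidate loci
    from strand-aware read profiles with rule-based retention and
    exclusion filters; annotates snoRNA structural elements (C/D boxes,
    terminal inverted repeats, two-hairpin H/ACA folds); predicts
    2'-O-methylation and pseudouridylation targets from antisense
    elements; classifies genomic organization (intronic, polycistronic
    cluster, intergenic) and cap / RNA polymerase III status; quantifies
    abundance (TPM), snoRNA/sdRNA stability ratios and the
    abundance-stability correlation; and benchmarks every stage against
    the simulation ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rcpp,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
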