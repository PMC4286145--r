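Package: codonscreen
Title: Compositional Codon-Usage Screening for Horizontally Transferred Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects compositionally atypical protein-coding genes in bacterial
    draft genomes by comparing per-gene relative synonymous codon usage (RSCU),
    GC and synonymous third-position GC content against the pooled all-gene
    background, flagging genes whose RSCU changes more than a fold threshold in
    more than a given fraction of the degenerate codons they use. Integrates
    best-hit taxonomy to classify candidates for horizontal gene transfer,
    reproduces standard genome-report statistics (N50, coding density, COG
    category tables), places taxa with neighbor-joining trees on Kimura
    2-parameter distances with bootstrap support, and simulates coding-sequence
    sets with controlled codon-usage structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
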