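Package: anchorkit
Title: Anchored Hybrid Enrichment Bait Design and Phylogenomic Matrix Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for target-capture phylogenomics of protein-coding loci:
    design of tiled hybridization bait sets from paired amino-acid and
    nucleotide orthogroup alignments; in-silico evaluation of target capture
    from assembled contigs with identity/coverage thresholds and paralog
    ambiguity filters; codon-aware quality control of recovered locus
    alignments (reading-frame inference, flank detection, frameshift
    masking); construction of completeness-filtered supermatrices with
    gene-by-codon-position partitions; four-cluster likelihood mapping of
    quartet support on the ternary simplex; and classification and collapse
    of branch support in trees.  A companion set of simulators generates
    synthetic inputs with recorded ground truth for every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
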