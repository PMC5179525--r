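Package: lrrkit
Title: Evolutionary Analysis of LRR Receptor-Like Kinase Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for genome-wide evolutionary analysis of the
    leucine-rich repeat receptor-like kinase (LRR-RLK) gene family and
    similar plant receptor-kinase families. Provides family-membership
    screening from homology hits and domain-architecture tables, scaffold
    mapping with tandem-duplication cluster detection validated against a
    phylogeny, midpoint rooting and support-thresholded subfamily
    classification, LRR-repeat and sequence-motif conservation summaries
    with per-column information content, intron/exon structure comparison,
    maximum-likelihood fitting of codon substitution site models
    (M0, M1a, M2a, M3, M7, M8) with likelihood-ratio tests and naive
    empirical Bayes identification of positively selected sites, FPKM
    expression summaries, and a synthetic-family simulator with full
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    phytools,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
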