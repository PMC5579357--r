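Package: phyloprof
Title: Phylogenetic Profiling, Dollo Parsimony and Motif Co-Occurrence
    Analysis of Protein Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative-genomics analysis of protein machineries
    across eukaryotic genomes: construction of phylogenetic profiles
    (presence/absence and copy number of orthologous groups over a fixed
    species catalog), pairwise co-evolution scoring with the Pearson/phi
    coefficient and interaction-enrichment threshold calibration,
    average-linkage clustering of profiles, Dollo-parsimony reconstruction of
    gene origins and losses on a rooted species tree, short-linear-motif
    scanning in sequences and alignments with hypergeometric co-occurrence
    tests, protein-set conservation statistics, and a seeded gene-content
    simulator (single origin plus per-branch stochastic loss, coupled pairs,
    multifunctional genes, planted motifs) that provides ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
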