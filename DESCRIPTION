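Package: bacedit
Title: Discovery and Characterization of A-to-I mRNA Editing in Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for discovering TadA-mediated A-to-I mRNA
    editing from bacterial RNA-seq: quality trimming, ungapped read mapping
    (or SAM ingestion), neighborhood-quality pileups, RNA-DNA difference
    calling, a replicate-consistent filter cascade producing oriented A>G
    editing sites, motif enrichment against a genome-sampled null, codon
    recoding annotation, 17-nt minimum-free-energy sliding-window structure
    analysis around edited adenosines, differential editing between strains,
    and conservation classification across species. Includes a synthetic-data
    generator that plants editing sites in YTACGAA motifs inside stem-loops
    so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
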