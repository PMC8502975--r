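Package: panGenomics
Title: Pan-Genome Analysis of Bacterial Strain Panels with Simulated Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative pan-genomics for small panels of bacterial strains:
    all-vs-all protein similarity with Smith-Waterman local alignment,
    ortholog gene-family clustering and presence-absence matrices,
    core/dispensable/strain-specific partitioning, permutation-median
    pan- and core-genome curves with Heaps-law and exponential regression
    and an open/closed verdict, fragment-based average nucleotide identity
    (ANI) with species grouping at the 95 percent boundary, single-copy-core
    neighbor-joining phylogenies with family bootstrap, and a horizontal
    gene transfer screen combining GC-content anomaly with gene-tree
    placement. A synthetic multi-strain generator with a known gene-family
    history, known tree and a plantable foreign-origin gene cluster provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings,
    IRanges,
    ape,
    igraph,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
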