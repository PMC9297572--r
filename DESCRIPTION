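Package: teconcord
Title: Concordance of Repeat Annotations and Transposable-Element Downstream Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Compares repeat-annotation sets produced by different repeat
    finders over fixed-width genome windows (binary presence encoding,
    complete-linkage clustering, abundant presence/absence patterns, pairwise
    base-level agreement, per-tool coverage) and carries the chosen annotation
    through the downstream transposable-element analyses of a genome project:
    per-class composition and chromosomal density profiles, repeat-gene
    overlap with full-containment and fractional-coverage rules,
    phylostratigraphic age-class contributions, multi-classifier consensus
    evaluation, and synteny-based detection of lineage-specific transposon
    insertions. A seeded synthetic-data generator emulates every input type
    with a ground-truth registry so the whole pipeline is testable without
    external genomes or repeat finders.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
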