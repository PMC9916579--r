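Package: mybevol
Title: Comparative Genomics of the Plant MYB Transcription-Factor Superfamily
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of the MYB transcription-factor
    superfamily across green plants: family identification and 1R-4R
    subfamily classification from Pfam domain hits, lineage copy-number
    statistics and orthogroup copy-number-divergence testing, Nei-Gojobori
    (1986) Ka/Ks estimation for duplicate gene pairs with Ks landscapes,
    expression-based classification of duplicate fates (sub-/neo-
    functionalized, asymmetrically expressed, or undiverged), gene-tree
    screening for plant-fungus horizontal gene transfer, and transposable-
    element context analysis with LTR insertion-time dating. Every pipeline
    input can be generated with planted ground truth by the bundled
    simulators, so all stages are testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    phangorn,
    phytools,
    limma,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
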