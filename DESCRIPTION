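Package: burstchrom
Title: Simulation and Analysis of an Embryonic Transposon Expression Burst
    and Its Chromatin Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study a transient burst of transposable-element (TE)
    expression in early embryos and the heterochromatin (H3K9me3) response it
    triggers. Includes a synthetic-data generator with full ground truth
    (genomes with planted non-reference TE insertions, RNA-seq, ChIP-seq,
    small RNA-seq and paired-end WGS reads); a two-tier read assigner that
    resolves reads to TE consensus families (with seeded random allocation of
    multimappers) or unique genome loci, with rpm normalisation; a
    discordant-read-pair insertion caller with a both-sides (1p1) support
    filter and directionality inference; insertion-centric signal matrices,
    metaprofiles, downstream-asymmetry scores, and windowed enrichment-based
    euchromatin annotation; negative-binomial differential testing of binned
    ChIP counts with insertion attribution; and small-RNA processing
    (adapter clipping, size selection, antisense piRNA profiling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
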