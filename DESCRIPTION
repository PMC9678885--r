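Package: regulomer
Title: Consensus Regulome Integration and Cell-Cycle Phenotyping for
    Transcription-Factor Competition Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for studying how a chimeric transcription
    factor competes with its native counterpart across the regulome. Builds
    high-confidence consensus binding sites from replicate ChIP-seq peak sets
    and open-chromatin supersets, annotates peaks to nearest genes with
    strand-aware signed distances, tests binding-by-expression enrichment with
    binned one-sided Fisher tests under Benjamini-Hochberg control, classifies
    dual-factor binding sites from CPM signal ratios, extracts cross-cell-line
    core target programs, runs preranked gene-set enrichment with a
    permutation null, integrates per-gene meta-analysis scores, and assigns
    mass-cytometry events to cell populations and cell-cycle phases with a
    batch self-organizing map plus rule-based metacluster annotation. A
    synthetic-data module generates every input with planted ground truth so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    mclust,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
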