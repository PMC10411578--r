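Package: stressDMR
Title: Differential DNA Methylation and Hydroxymethylation Region Analysis
    Across Social Defeat Stress Paradigms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for calling stress-induced differentially
    methylated (5mC) and hydroxymethylated (5hmC) regions from replicate
    enrichment peak sets using windowed-overlap replicate consensus and
    presence/absence differential calling, quantifying regions as counts per
    million with log2 fold changes, annotating regions to nearest genes and
    genomic features, linking modification changes to concomitant gene
    expression changes, classifying region trajectories across an
    acute-chronic-longitudinal stress time course, and scoring social
    interaction and sucrose preference behavioral phenotypes. Ships a
    synthetic-data generator with planted ground truth so every stage is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
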