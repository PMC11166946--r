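Package: spacefrail
Title: Frailty, Sarcopenia and Metabolic Flux Signatures in Spaceflight Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for screening aging, frailty and sarcopenia
    signatures in spaceflight transcriptomics. Provides frailty-biomarker
    differential-expression filtering with cross-species ortholog translation
    and overlap partitioning; gene-set enrichment with a weighted running-sum
    score and permutation-normalized enrichment scores; a sarcopenia-predictor
    screen combining per-gene Mann-Whitney tests, single-gene
    k-nearest-neighbor Mean Accuracy Scores, co-expression module
    eigengene-trait correlation and hypergeometric over-representation
    curation; a context-specific constraint-based metabolic flux simulation
    with expression-driven confidence tiers, NAD-sink-first optimization and
    Van der Waerden group comparison; and astronaut time-course plus
    single-cell frailty-gene summaries. Every input can be emulated by the
    bundled synthetic-data generators with known planted structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Matrix,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
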