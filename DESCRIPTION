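Package: irmdma
Title: Internal-Reference Ratio Normalization for Differential Microbiome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Screens a host-specific internal reference microorganism (IRM)
    from companion-plant-matched rhizosphere genus tables, re-normalizes all
    genera to the IRM as relative community quantities (RCQ), and re-screens
    differential genera with Wilcoxon and Kruskal-Wallis rank tests
    (IRMRA-DMA), alongside the classic relative-abundance workflow (PA-DMA).
    Includes a synthetic amplicon-community simulator with known ground truth
    and a benchmark quantifying the compositional false positives that ratio
    normalization removes, plus small utilities for plate-assay indices and
    qPCR fold changes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
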