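Package: tmdscreen
Title: Analysis and Simulation of Split Beta-Lactamase Transmembrane
    Helix Interaction Screens
Version: 0.1.0
Authors@R:
    person("Screen", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative toolkit for genetic screens that report
    transmembrane-domain (TMD) interactions through reconstituted
    beta-lactamase activity. Fits decreasing Hill dose-response curves to
    ampicillin kill data and extracts LD50 values with replicate
    aggregation, reference normalization and affinity classification;
    enumerates a focussed single-charge poly-leucine (L19GG) combinatorial
    TMD library and assembles hybrid reporter proteins; computes
    charge-pair, positional and spacing statistics with exact
    overrepresentation factors over the enumerated library; and simulates
    noisy plate-reader curves plus the two-step ampicillin selection so
    that every analysis stage can be exercised end to end on synthetic
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
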