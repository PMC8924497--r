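Package: csrspectra
Title: Ecological Strategy Spectra of Plant Communities from Leaf Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for positioning vascular plant species in Grime's
    competitor / stress-tolerator / ruderal (CSR) triangle from three leaf
    traits (leaf area, specific leaf area, leaf dry matter content) with a
    StrateFy-style global calibration, classifying species into four
    strategy groups by the midpoint partition of the ternary plot, building
    ecological strategy spectra (proportions of species per group) for
    plots and forest types, and relating those spectra to species diversity
    (richness, stem abundance, Shannon-Wiener index) through standardized
    regression coefficients, Hellinger-transformed redundancy analysis with
    Monte Carlo permutation tests, and adjusted-R2 variance partitioning.
    Includes a synthetic forest-landscape generator with a tunable
    diversity-strategy coupling so the full analysis chain can be exercised
    and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    optparse
Config/testthat/edition: 3
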