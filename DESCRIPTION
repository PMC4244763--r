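Package: nestkit
Title: Nestedness Measures, Null Models and Adaptive Significance Testing
    for Bipartite Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures the nestedness of binary and weighted bipartite
    interaction matrices with seven complementary scores (NODF, weighted
    NODF, Manhattan distance, nestedness temperature, configuration-model
    disassortativity, discrepancy and spectral radius), and tests their
    statistical significance against nine null-model randomisation
    schemes.  Ensembles of null matrices can be of fixed size or sized
    adaptively by growing two parallel groups until a Mann-Whitney U-test
    can no longer tell them apart.  Results are reported as p-values,
    z-scores and normalised temperatures, with the direction of
    increasing nestedness detected automatically for every measure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
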