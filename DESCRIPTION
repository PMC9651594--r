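Package: privgoods
Title: Eco-Evolutionary Consumer-Resource Models of Partially Privatized
    Public Goods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic consumer-resource models for the ecology and
    evolution of partially privatized public goods in well-mixed microbial
    communities. Implements a general single-resource producer/non-producer
    model and a nitrogen-fixation/siderophore colimitation model for marine
    cyanobacteria, together with the analysis machinery built on them:
    single-strain equilibria, zero net growth isoclines (ZNGIs), supply-point
    mapping and impact vectors, invasion analysis and pairwise competition
    classification, analytic privatization bounds, seeded random-parameter
    viability and invasibility screens, and adaptive dynamics (pairwise
    invasibility plots, evolutionarily stable strategies, ZNGI envelopes and
    critical nitrogen-to-siderophore supply ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
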