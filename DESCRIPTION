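Package: rapbeef
Title: Rapid Appraisal of Beef Supply Chain Sustainability by Anchored Ordination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores beef supply chain entities (farm and slaughterhouse
    systems) on economic, social and environmental sustainability
    indicators, maps raw measurements onto six-point ordinal scales, and
    ordinates the score matrices with an anchored two-dimensional
    multidimensional scaling (MDS) that projects every entity onto a
    0-100 sustainability index between a "bad" (0) and a "good" (100)
    reference profile.  Includes goodness-of-fit statistics (S-Stress and
    R squared), drop-one attribute leverage analysis (RMS), Monte Carlo
    stability analysis of the ordination, and Delphi-round consensus
    analysis via the tie-corrected Kendall coefficient of concordance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
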