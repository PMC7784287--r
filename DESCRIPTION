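Package: olfactomap
Title: Topographic Analysis of Olfactory-Bulb Odor Maps and Amyloid Pathology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for angle-resolved analysis of the mouse olfactory bulb:
    trial-averaged dF/F0 odor activity maps from widefield fura-2 movies,
    arc-length angular registration of the glomerular layer, DAB
    color-deconvolution immunoreactivity profiles, odor-map spatial
    correlation clustering, angle-matched cross-modal Spearman correlation,
    and behavioral indices (zone-occupancy performance index, normalized
    food-seeking latency, Y-maze alternation). Includes a seeded synthetic
    data generator that emulates the raw inputs of a 5xFAD olfactory
    pathology study, so every pipeline stage can be validated against
    planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
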