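Package: placecode
Title: Place and Speed Coding Analysis for Calcium Imaging of Hippocampal Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for one-photon calcium imaging of hippocampal
    CA1 populations recorded during free exploration of linear enclosures.
    Classifies place cells by spatial mutual information against circular-shift
    permutation nulls, segments place fields from occupancy-normalized activity
    maps, quantifies remapping under mid-session enclosure rotation and
    rescaling, classifies speed cells and decodes running speed with
    block-cross-validated linear models, detects population coactivity events,
    and matches cells across days from spatial footprints to measure turnover
    and coding stability. Includes a synthetic-session generator with known
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
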