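Package: duravasc
Title: Morphometry of Dural Blood and Lymphatic Microvascular Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Skeleton-graph morphometry for 2D microvascular images of the
    cranial dura mater. Converts class-labelled vessel masks (arteriole,
    venule, undetermined, lymphatic) into one-pixel-wide centerline graphs
    with typed nodes (branching, transition, endpoint), computes
    complete-segment metrics (length, arc-chord tortuosity), vessel area
    fractions, alpha-smooth-muscle-actin coverage and podoplanin-positive
    lymphatic measures, aggregates per-image records to per-animal means and
    runs two-group comparisons. Includes a synthetic confocal-scene
    generator with exact analytic ground truth for validation, and an
    end-to-end simulate-quantify-compare pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
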