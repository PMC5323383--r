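Package: dockscape
Title: Docking-Pose Landscape Analysis for Enzyme Mutation Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence- and structure-guided prioritization of enzyme point
    mutations. Detects subfamily-specific positions in a two-group protein
    multiple sequence alignment, merges them with positively selected sites
    from branch-site analyses, screens candidates against the active-site
    geometry and hydrogen-bonding network of a structural model, enumerates
    physicochemical mutation panels, and analyses docking-pose ensembles as
    an RMSD-binding-energy landscape whose group-III representative energy
    predicts whether a mutation raises or lowers catalytic activity. Includes
    a synthetic-data generator that emulates every input so the full pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
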