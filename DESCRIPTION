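Package: liveqibc
Title: Multigenerational Single-Cell Lineage Tracking with End-Point
    Multiplexed Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct multigenerational single-cell lineages from
    time-lapse imaging features, stage the cell cycle from PCNA replication
    foci counts, align live-cell tracks to end-point multiplexed (4i)
    immunofluorescence panels, score sister-cell heterogeneity with
    categorical thresholds, classify polyploidization routes
    (endoreplication versus rereplication), and detect highly variable genes
    in single-cell RNA-seq with a mean-variance residual statistic. Includes
    a ground-truthed synthetic-data generator emulating lineage movies,
    end-point staining panels, and UMI count matrices, plus a built-in
    nucleus segmentation and focus-detection path for rendered or
    user-supplied image stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    grDevices,
    graphics,
    Matrix,
    jsonlite,
    yaml,
    ape,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
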