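Package: spinemorph
Title: Dendritic Spine Morphometry for Eel Olfactory-Bulb Granule Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Rule-based morphometric classification of dendritic spines
    (mushroom, long thin, stubby, filopodia) from head and neck geometry,
    spine density per 10 micrometres of dendritic trunk, and the
    nonparametric cross-group statistical battery (tie-corrected
    Kruskal-Wallis with Dunn's pairwise Z post hoc) used to compare
    granule-cell spine populations across the continental life stages of
    the European eel (Anguilla anguilla). Includes SWC-dialect
    reconstruction input and output, a diameter-profile spine measurement
    algorithm, and a calibrated synthetic study generator so the whole
    pipeline is testable without the original Golgi-Cox material.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
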