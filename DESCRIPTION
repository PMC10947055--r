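Package: maculadev
Title: Macular Layer Deviation Mapping and Cluster Agreement in Glaucoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing colocalised glaucomatous change across macular
    retinal layers from en-face optical coherence tomography thickness maps.
    Builds demographics-matched normative deviation maps for the ganglion
    cell-inner plexiform layer (GCIPL), inner nuclear layer (INL) and outer
    retinal complex (ORC); classifies 10-2 visual fields into defect types
    using the Hodapp-Parrish-Anderson criterion; clusters deviation grids with
    within-groups hierarchical linkage refined by a d-prime separability
    criterion; quantifies between-layer agreement of defective regions with
    Cohen's kappa; and correlates within/outside-defect differences with
    visual-field severity indices. Includes a synthetic cohort generator with
    known ground truth so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
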