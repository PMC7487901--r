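Package: rhoquant
Title: Quantitative Imaging and Cytometry for Rho GTPase Cell Biology Assays
Version: 0.1.0
Authors@R:
    person("Maintainer", "rhoquant", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measurement procedures for the standard cell-biology assays used
    to study Rho GTPase signalling in migrating and invading cells:
    ratiometric FRET biosensor quantification (FRET/donor ratio images and
    fold change to control), punctate-structure detection for focal adhesions
    and invadopodia via contrast-limited adaptive histogram equalization and
    Laplacian-of-Gaussian filtering, the fluorescent-gelatin matrix
    degradation index, wound-healing closure rates and single-cell motility
    statistics, DNA-content cell-cycle gating, Annexin/PI quadrant
    classification, gel densitometry fold change, and sphere/tissue
    morphometry. A synthetic-scene simulator generates every input with a
    ground-truth record, providing an oracle for validating each stage. Reads
    and writes plain TIFF and CSV and is driven by YAML configurations for
    reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
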