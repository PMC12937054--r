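Package: cellogram
Title: Cellographic Peak Detection and Feature Processing for
    Direct-Infusion Single-Cell Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Processing engine for continuous direct-infusion single-cell
    metabolomics acquisitions ("cellograms"). Reads and writes centroided
    mzML, detects per-cell sampling events on an extracted ion chronogram
    with signal-to-noise thresholds and a refractory period, aligns
    high-resolution m/z values into feature groups within a ppm tolerance
    in two stages (within and across cell events, and across files),
    applies a cumulative statistical filter cascade (fold change, detection
    frequency, 13C deisotoping, internal-standard and solvent-blank
    exclusion, mass defect filtering), supports targeted matching and
    internal-standard quantification, and classifies extracted-ion
    chronogram profiles into endogenous and background species with a
    trainable image classifier. A fully seeded cellogram simulator with
    ground truth makes every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mzR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    jsonlite
Config/testthat/edition: 3
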