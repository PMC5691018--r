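Package: pioncal
Title: Signal-Strength Ion Recombination Corrections for FFF Beam Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures the ion collection-efficiency correction (Pion) of an
    ionization chamber by the two-voltage technique, calibrates Pion as a
    linear function of a renormalized signal strength, and applies the
    calibration to correct relative dosimetry of flattening filter-free
    (FFF) radiotherapy beams: percent depth dose, tissue-maximum ratio,
    off-axis ratio, relative dose factor, 50%-isodose field width, and the
    quality-conversion (kQ) chain of absolute dose calibration. Includes a
    synthetic FFF beam-scan generator that is algebraically self-consistent
    with a prescribed Pion(signal) relation, CSV/JSON readers and writers
    for scan curves and calibrations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
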