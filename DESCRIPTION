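Package: woundsight
Title: Quantification of Exo-Endocytic Dynamics During Plasma Membrane Wound Repair
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying laser-ablation plasma-membrane repair
    experiments from multi-channel time-lapse fluorescence movies: punctae
    detection, concentric-ring event counting with baseline and area
    normalization, dye-influx resealing kinetics and classification,
    object-based colocalization, nearest-neighbor association between
    exocytic and endocytic events, optical-tweezers tether-force plateau
    extraction, and a line-tension/membrane-tension hole-energetics model.
    Includes a synthetic movie and force-trace generator with ground truth
    so every stage of the analysis is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
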