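Package: ductokym
Title: Kymograph Analysis of Duct Contractility from Time-Lapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies smooth-muscle contractility of tubular ducts (such as
    the epididymal duct) from transillumination time-lapse image stacks.
    Extracts kymographs (virtual sections through the time stack) along
    user-defined or automatically placed analysis lines, tracks the duct
    walls to a sub-pixel diameter trace, detects phasic contraction events
    and reports beats-per-minute frequencies, estimates peristaltic wave
    speed from event latencies across axial stations and luminal flow from
    longitudinal kymographs, and compares drug epochs with paired
    nonparametric statistics (Friedman test with Dunn's post hoc, implemented
    from the rank formulas, with an exact permutation option). Includes a
    synthetic movie simulator with full ground truth for validation, TIFF
    stack I/O, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tiff,
    yaml,
    jsonlite,
    MASS,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
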