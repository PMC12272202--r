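Package: vasconn
Title: Macrovascular Contributions to Resting-State fMRI Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify how large cerebral arteries and veins
    contribute to resting-state functional-connectivity maps. Provides
    vessel-mask engineering (fusion of multi-orientation angiographic
    segmentations, resampling to the fMRI grid, artery/vein splitting,
    perivascular shells), minimal BOLD preprocessing (nuisance
    regression, bandpass, spatial smoothing), blocked seed-target
    correlation metrics (degree, signed strength and spatial variance)
    for artery/vein/gray-matter category pairs, macrovascular-to-GM
    ratio maps, distance-resolved perivascular profiles, resting-state
    network occupancy, and a seeded synthetic phantom carrying a
    band-limited systemic low-frequency oscillation with opposite sign
    in arteries and veins so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
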