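Package: quietscope
Title: Design and Analysis Tools for Silent Acousto-Optic Two-Photon Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A toolkit for acousto-optic deflector (AOD) based two-photon
    laser-scanning microscopy in auditory neuroscience. Provides closed-form
    paraxial calculators for chirped AOD raster-scan design (line time, frame
    geometry, field of view, multi-layer depth shift, transition dark band,
    ultrafast-pulse dispersion), calibrated acoustic power-spectral-density
    analysis with species-specific auditory excitation patterns and hearing
    threshold comparison, construction of calibrated tone-pip stimuli and
    frequency-by-level mapping sessions, a calcium-imaging analysis pipeline
    from movies and ROI masks to dF/F traces and frequency-response-area (FRA)
    maps with best-frequency/best-level extraction, and a ground-truth
    synthetic session simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
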