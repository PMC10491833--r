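Package: circlight
Title: Circadian and Brightness Metrics for Light Source Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spectral-integration metrics for indoor white lighting:
    circadian light (CL_A, versions 1.0 and 2.0) and circadian stimulus
    (CS) with the warm/cold opponent-channel branch, melanopic equivalent
    daylight illuminance (mEDI), a nocturnal melatonin-suppression
    conversion, and spectral brightness models (equivalent luminance,
    B2, and the TU Darmstadt brightness model). Includes the bundled
    standard observer functions, SPD file input/output, chromaticity /
    correlated colour temperature / Duv colorimetry, a seeded synthetic
    light-source ensemble generator spanning incandescent, fluorescent,
    LED and daylight classes, and a correlation pipeline that regresses
    and cross-tabulates all metrics at fixed photopic illuminance levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
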