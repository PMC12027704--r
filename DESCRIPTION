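Package: chromacal
Title: Color Fidelity Assessment and Calibration for Dermatological Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies color reproduction accuracy of dermatological imaging
    systems and their light sources. Measures ColorChecker chart photographs
    and reports CIELAB and CIEDE2000 color deviation summaries per patch;
    scores light sources from spectral power distributions via correlated
    color temperature, the CIE 13.3 color rendering index, and a television
    lighting consistency score built on a model camera/display chain;
    estimates gray-card white-balance gains and applies exposure-anchored
    corrections; and generates fully seeded synthetic chart images, gray-card
    scenes, and Planckian/daylight/LED spectra so every stage can be tested
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    tiff,
    jsonlite
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
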