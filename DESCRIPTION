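Package: craniomorph
Title: Landmark Placement Error and Ontogenetic Allometry for Embryonic
    Mouse Craniofacial Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landmark-based geometric morphometrics of embryonic
    mouse craniofacial surfaces between embryonic days 10.5 and 12.5.
    Encodes a standard 36-landmark scheme (6 midline points and 15
    bilateral pairs) with anatomical subset and trouble-landmark
    annotations, reads and writes landmark configurations in TPS and CSV
    formats, and simulates balanced multi-observer landmarking designs
    with specimen-level shape variation, observer-specific bias, trial
    noise, and linear ontogenetic allometry. Quantifies intraobserver and
    interobserver landmark placement error, fits a balanced three-factor
    placement ANOVA per embryonic age, flags unreliable landmarks, and
    performs generalized Procrustes superimposition followed by
    multivariate regression of shape on centroid size, including
    regression scores, per-landmark ontogenetic vectors, and a
    landmark-subset-removal robustness experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
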