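Package: spinalrhythm
Title: Fictive Locomotion Rhythm, Coordination and Calcium Map Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for drug-induced fictive locomotion recorded from
    the isolated neonatal mouse spinal cord. Detects bursts in rectified
    ventral-root envelopes and derives the standard locomotor parameters
    (frequency, burst duration, cycle period, duty cycle, amplitude) with their
    coefficients of variation; computes cycle-by-cycle phase relationships
    between root pairs with circular statistics (mean angle, vector length,
    Rayleigh and Watson-Williams tests); and implements a grid-ROI calcium
    imaging pipeline (field normalization to 500 x 400 pixels, 500-ROI tiling,
    dF extraction, autocorrelation oscillation-index maps and cross-correlation
    phase maps). A synthetic-data module generates recordings and movies with
    fully known ground truth so every analysis stage is testable end to end.
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
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
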