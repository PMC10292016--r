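Package: ppgfiducial
Title: Fiducial Point Extraction and Pulse-Wave Feature Tables for
    Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates the fourteen named fiducial points of a single
    photoplethysmography (PPG) beat and its first three derivatives (the
    velocity, acceleration and jerk plethysmograms), using zero-phase
    Chebyshev type-II bandpass preprocessing, skewness-based signal
    quality screening, onset-bounded beat extraction and a three-case
    algorithm for the acceleration-waveform c and d waves driven by jerk
    zero-crossings.  Assembles a 30-column feature table (15 magnitudes
    and 15 time-domain values per beat), writes the standard output file
    suite as CSV, and provides a detector evaluation framework
    (sensitivity, positive predictivity, error rate, accuracy) together
    with a synthetic PPG generator with analytically known ground-truth
    fiducials for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
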