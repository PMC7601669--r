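Package: poretrace
Title: Resistive-Pulse Event Analysis for Conical Track-Etched Nanopores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule resistive-pulse recordings
    from conical track-etched nanopores: conical-pore conductance geometry,
    zero-phase Butterworth low-pass filtering, Savitzky-Golay baseline
    correction of drifting traces, 3-sigma current-blockade event detection,
    five-feature event characterization (relative blockade, dwell time, area,
    left/right flank slopes), distribution/correlation/regression diagnostics,
    and support-vector-machine discrimination of DNA samples with paired
    two- versus five-feature cross-validated comparison. Includes a synthetic
    trace generator with ground-truth events for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
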