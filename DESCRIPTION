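Package: polyqrs
Title: QRS Onset and Offset Delineation by Polygonal Approximation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the onset and offset fiducial points of the ECG QRS
    complex by representing each R-R section as a small set of polygonal
    vertices (curvature-based initial selection, sequential split
    refinement, and dynamic-programming position optimization), building a
    monotone cumulative amplitude-change auxiliary signal over those
    vertices, and scoring candidate vertices with amplitude, time and
    angle features. Includes a Pan-Tompkins R-peak detector, Butterworth
    band-pass preprocessing, a synthetic ECG generator with exact
    fiducial ground truth and configurable noise, an evaluation harness
    for annotated records, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
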