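Package: rdknotch
Title: Notched Random-Dot Kinematograms for Criterion-Free Measurement
    of Motion Transparency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for synthesising random-dot kinematograms (RDKs) whose
    dot speeds or directions are drawn from uniform distributions with a
    central notch removed, under matched-range and matched-global-mean
    constraints; for simulating three-alternative odd-one-out (oddity)
    sessions and maximum-displacement (Dmax) direction-discrimination
    sessions against model observers; and for turning the resulting
    session logs into proportion-correct performance tables and
    psychometric fits with thresholds at a stated criterion. Distribution
    construction supports symmetric notches, exponential-tilt weighting to
    hit target band means, bandwidth families, and directional gaps, all
    validated against the matched-statistics constraints the oddity design
    requires.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
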