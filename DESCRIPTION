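Package: nbslvf
Title: Natural Blind Spot Location and Pointwise Analysis of 24-2 Visual Fields
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the natural blind spot location (NBSL)
    reported by automated perimetry on the 24-2 test pattern: cohort
    inclusion filtering with reliability and normality criteria,
    Gaussian-process estimation of a continuous NBSL frequency surface
    from a gridded count table, count-weighted spatial summary statistics,
    NBSL-refraction correlation, and pointwise pattern-deviation difference
    and regression maps with false-discovery-rate control, together with a
    seeded synthetic cohort generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, grDevices, graphics, jsonlite
Suggests: testthat (>= 3.0.0), kernlab, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
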