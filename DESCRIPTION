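Package: cwchord
Title: Raytraced Translation Between the Chang-Waring Chord and Angle Alpha
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric raytracing of a two-surface aspheric cornea with a
    decentred aperture stop to locate the pupil-centre ray and the first
    Purkinje reflex as seen by a coaxially fixating anterior-segment
    instrument, yielding the Chang-Waring (CW) chord. Includes
    entrance-pupil footprint tracing with moment-based constraining-ellipse
    fitting, truncated-normal Monte-Carlo machinery emulating a large
    clinical Casia2 biometry cohort, and a stepwise multivariable linear
    translation model between the CW chord and the incident ray angle
    (angle Alpha), in both directions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
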