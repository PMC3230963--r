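Package: segmoment
Title: Direct Measurement of First-Order Body Segment Mass Moments
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates the first-order mass moment (mass times lever arm of
    the centre of mass about a rotation axis) of a rigid body segment from
    reaction-board measurements of the whole-system centre of mass taken
    before and after rotating the segment in the horizontal plane by a known
    angle. Provides the planar rotation-elimination estimator, computation of
    the whole-system centre of mass from three support-point scale readings,
    a forward statics simulator with instrument and digitisation noise
    models, Monte Carlo and first-order analytic uncertainty propagation,
    and a session CSV/JSON interface with a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
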