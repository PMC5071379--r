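Package: fieldcenter
Title: Bisection and Stiffness Models of Force-Field Center Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how humans locate the center of a weak
    elastic force field rendered by a haptic device. Implements two
    competing perceptual models -- the bisection model, in which the
    perceived center is the (weighted) midpoint of the positions where
    the force reaches the detection threshold, and the stiffness model,
    in which the field is extrapolated to zero force from supra-threshold
    probes under a Stevens power-law transducer -- together with a joint
    bias-and-variability least-squares fit, literature-threshold
    prediction bands for model adjudication, a trial preprocessing chain
    (endpoint extraction, zero-crossing center estimation, two-criterion
    outlier rejection, per-condition summaries), and a synthetic
    experiment generator that emulates bilateral and unilateral
    force-field designs for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
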