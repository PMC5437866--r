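Package: surveyerr
Title: Characterising False-Positive Errors in Repeated Species Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying false-positive (misidentification) errors
    in repeated presence-only site surveys. Classifies survey records against
    a site reference into true-positive, false-positive, cautious (genus-only)
    and mythical (non-existent name) categories; estimates per-species
    detection probabilities and per-observer error rates; combines multiple
    surveys under acceptance thresholds by bootstrap resampling and computes
    sensitivity and specificity with a false-positive-pool true-negative
    convention; tests false-positive status for phylogenetic signal with the
    D statistic for binary traits (tip-permutation and Brownian-threshold
    calibrations); models false-positive probability against regional
    occupancy with a logit-link GLM; and generates fully synthetic survey
    worlds with known ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
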