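Package: mirevtd
Title: Executable Minimum Information Standard for Vector Trait Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Makes the MIReVTD minimum information standard for reporting
    disease-vector trait data machine-checkable. Provides a machine-readable
    schema of the standard's minimum descriptors (organism, trait
    description, axes of variation), strict UTF-8/RFC 4180 CSV input and
    output, a rule engine that flags completeness and formatting violations
    with severities and rule anchors, converters between individual-level
    and aggregated representations, a synthetic-data generator with known
    ground truth, and Bayesian Briere-1 thermal-performance-curve fitting by
    adaptive random-walk Metropolis that demonstrates the information cost
    of aggregating individual observations into group means.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
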