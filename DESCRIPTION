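Package: fedsdc
Title: Federated Analysis with Active Statistical Disclosure Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a multi-site "analysis to the data" platform: in-process
    data-holding nodes that execute whitelisted assign/aggregate commands under
    active statistical disclosure controls (cell suppression, subset-size and
    model-dimension filters, string sanitization), an analyst client that pools
    non-disclosive summary statistics including an exact federated generalized
    linear model fitted by exchanging score vectors and information matrices,
    privacy-preserving plot obfuscation (k-nearest-neighbour centroids and
    seeded Gaussian noise), and an append-only audit log with detectors for
    multi-step disclosure attacks such as one-row difference attacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
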