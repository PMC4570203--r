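Package: tccross
Title: Cross-Classification Comparison of Transporter Family Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing a hierarchical transporter classification
    (TC numbers, superfamilies) against a domain-family classification
    (family accessions grouped into clans). Finds proteins classified in
    one system but absent from the other, builds family-by-family match
    matrices with SVG output and pattern detection, maps superfamilies to
    clans by majority rule, screens candidate entries by transmembrane
    topology and alignment E-value windows, and scores pairwise homology
    against a shuffled-sequence Monte Carlo null expressed in standard
    deviations. Ships a seeded synthetic-fixture generator so every
    pipeline stage can be exercised against a planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    grDevices,
    jsonlite,
    methods,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
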