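Package: ssir
Title: Superposing Significant Interaction Rules for Two-Class Sample Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based ranking of two-class sample libraries described by
    categorical fingerprints, such as absent/marginal/present microarray
    expression calls. Conjunction rules over descriptor levels (optionally
    negated) are enumerated combinatorially, scored with exact hypergeometric
    tail p-values, and the significant ones are superposed into a consensus
    voting model that ranks training and external samples. Includes exact
    leave-one-out cross-validation with cached rule information, a
    label-randomization (Y-scrambling) test with Gaussian summary, a seeded
    synthetic-library generator with planted rules, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
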