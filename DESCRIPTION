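Package: forensicBN
Title: Bayesian Networks for the Forensic Database Search Problem
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates the probative value of a DNA 'database hit': the
    strengthening of a case against a suspect who was found by trawling a
    database of n profiles drawn from a closed population of N potential
    sources, given a random match probability gamma. Provides a small exact
    discrete Bayesian-network engine, builders for the island-problem and
    database-search networks, closed-form posterior and likelihood-ratio
    calculators, a brute-force individual-level enumeration oracle for
    cross-validation, and a command-line interface. Posterior source
    probabilities and the database-search likelihood ratio
    (N-1)/(N-n) are computed both by network inference and by formula, and
    the two routes are checked against each other.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
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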