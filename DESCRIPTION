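Package: casematch
Title: Optimal Case-Control Matching With and Without Replacement for
    Registry Data
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fast, deterministic 1:n case-control matching for
    primary-care registry extracts. Cases and controls are matched
    exactly on categorical variables (sex, practice, yearly contact
    group), within calipers on varying variables (age, follow-up,
    comorbidity index), and controls are assigned to cases by an
    iterative least-pool-first rule that minimises the total matched
    distance, with or without replacement of controls. Includes
    conditional logistic regression for the matched sets, a factorial
    scenario engine for sensitivity analyses of the odds ratio, a
    synthetic registry generator with a known conditional odds ratio
    for validation, and exhaustive assignment oracles for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    survival,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
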