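Package: dissolkin
Title: Dissolution Profile Comparison, Drug-Release Kinetics and
    Liquisolid Formulation Arithmetic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational layer of sustained-release tablet
    development: model-independent dissolution profile comparison via the
    difference factor f1 and similarity factor f2 with an FDA-style
    equivalence rule; fitting and selection of zero-order, first-order,
    Higuchi and Korsmeyer-Peppas release models scored by R-squared and
    mean percentage error, with mechanism classification from the
    diffusional exponent; liquid load factor and percent-by-weight
    arithmetic for liquisolid and Liqui-Mass dosage forms; powder
    flowability (Carr's index, angle of repose) and tablet friability
    metrics with compendial classification scales; and a seeded generator
    of synthetic two-stage (gastric/intestinal pH) dissolution experiments
    so every stage of the pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
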