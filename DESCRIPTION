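Package: lotshift
Title: Detecting Faunal Change from Natural History Collection Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting faunal change (introductions, range
    expansions and long-term declines) from lot-level natural history
    collection occurrence records. Provides a Darwin-Core-style reader and
    a staged curation cascade (georeferencing against an in-dataset
    gazetteer, synonym resolution, spatial and taxonomic filtering), a
    Poisson regression check that record counts track independent
    abundance categories, a binomial lower-tail test for declining
    species against the collection-wide post-cutoff deposition rate, a
    first-record screen for potential neozoa with a spatio-temporal
    artefact check, relative observation trend regressions against higher
    taxonomic ranks with an exclusion-region sensitivity rule, and a
    generative simulator of the pulsed museum collecting process with
    planted species dynamics that provides ground truth for every
    detector.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tibble
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
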