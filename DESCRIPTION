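Package: trawlniche
Title: Catch-Weighted Thermal Niche and Life-History Analysis for
    Bottom-Trawl Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Survey-based environmental-preference and life-history
    analysis for demersal fishes sampled by seasonal bottom-trawl
    surveys. Computes catch-weighted niche statistics (thermal bias,
    Steno index, weighted cumulative distribution functions and
    occupancy intervals for temperature and depth), fits logistic
    length-maturity ogives by in-package iteratively reweighted least
    squares with bootstrap confidence intervals for the length at 50%
    maturity, fits allometric length-weight relationships, summarises
    stomach contents (vacuity, frequency of occurrence, weight
    percentages), delineates subgroup habitat envelopes and their
    overlap, and builds annual catch-per-tow abundance indices. A
    configurable synthetic survey generator (Gaussian thermal field,
    Poisson catches under a Gaussian thermal response, protocol-faithful
    biological subsampling) makes every stage testable without access to
    the original survey database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
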