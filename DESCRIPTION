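Package: weedpath
Title: Weed Diversity, Herbicide Intensity and Their Mutual Influence in
    Field Trials
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for randomized-block herbicide field trials in
    winter wheat: Hill-series (Renyi) weed-diversity profiles with
    alpha/gamma partitioning, the treatment frequency index (TFI) as a
    herbicide-intensity metric, exact all-pairs comparisons of
    Friedman-type ranked data with compact letter displays, and a
    multi-group recursive path model quantifying how autumn weed diversity
    and density drive herbicide intensity, which in turn drives summer
    diversity.  Cross-group equality constraints are selected stepwise by
    likelihood-ratio tests.  A seeded synthetic-trial generator emulates
    the study design (15 fields, four treated plot groups plus an
    untreated control) in a structural mode driven by the path equations
    and a mechanistic mode driven by a simplified dose-response decision
    rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    vegan
Config/testthat/edition: 3
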