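Package: knockr
Title: Exhaustive Enumeration of Growth-Coupled Knockout Strategies in
    Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based strain design by complete, pruned enumeration of
    reaction (or gene) knockout strategies that couple overproduction of a
    target metabolite to growth. Provides flux balance analysis and flux
    variability analysis on a built-in bounded-variable simplex kernel,
    model preprocessing (blocked reactions, dead-end metabolites, essential
    reactions, the removable candidate set), a depth-first traversal that
    prunes the combinatorial search space without losing solutions, gene-level
    translation of reaction strategies with co-knocked-out reaction sets, and
    strain-ranking metrics (production envelopes, yield, substrate-specific
    productivity, strength of growth coupling, CO2 exchange, linear MOMA).
    Reads BiGG-style JSON and SBML Level 3 FBC models; results are returned
    as tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
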