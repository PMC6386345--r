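Package: chemotext
Title: Rule-Based Text Mining of First-Line Systemic Treatment from
    Cancer-Registry Free Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies free-text treatment fields from population-based
    cancer registries into eight first-line systemic treatment categories
    for stage IV non-small cell lung cancer (platinum doublets,
    pemetrexed-based, bevacizumab-based, pemetrexed plus bevacizumab,
    single agents, tyrosine kinase inhibitors, no treatment, unknown)
    using a curated drug lexicon with brand names, abbreviations and
    misspellings, regular-expression mention matching with negation and
    uncertainty detection, and a fixed-precedence sequential search order.
    Includes a validation module (percent agreement, Cohen's kappa,
    sensitivity, specificity, predictive values, error counts with
    confidence intervals), a synthetic registry-text generator with known
    gold labels for end-to-end testing, and command-line entry points for
    classify/evaluate/simulate pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
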