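Package: offsetElicit
Title: Structured Expert Elicitation of Biodiversity Offset Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for converting structured expert elicitations into
    probabilistic estimates of biodiversity-offset outcomes. Implements the
    trial-roulette (histogram) elicitation data model, least-squares fitting of
    normal and rescaled-beta subjective probability distributions to binned
    judgements, reference-benchmark condition scoring, Monte-Carlo pooling of
    averted loss, management gain and total benefit across an expert panel,
    per-expert optimism/pessimism diagnostics, and a boosted-regression-tree
    analysis of aggregate condition scores with normalised relative influence,
    partial dependence and ensemble prediction. A synthetic site-pool and
    expert-panel generator with known ground truth supports end-to-end testing
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
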