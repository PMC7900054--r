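Package: metafragility
Title: Fragility Index and Fragility Quotient for Meta-Analyses of
    Dichotomous Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the fragility index and fragility quotient for
    statistically significant meta-analyses of dichotomous outcomes.
    Implements the single-trial fragility index (iteratively adding
    events until a two-sided Fisher exact test is no longer significant),
    its meta-analytic generalisation (the minimal number of event-status
    modifications across included trials after which the pooled
    confidence interval includes the null), fixed-effect Mantel-Haenszel
    and random-effects DerSimonian-Laird pooling of relative risks and
    odds ratios, corpus-level summary statistics (medians with
    interquartile ranges, cumulative-count curves, Pearson correlations
    with Fisher-z confidence intervals), and a seeded synthetic corpus
    generator so the whole pipeline can be exercised without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    yaml,
    optparse
Config/testthat/edition: 3
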