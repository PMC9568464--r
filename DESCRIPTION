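Package: informedBF
Title: Informed Bayes Factors and Prior Sensitivity Analysis for
    Correlation and t-Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-sided Bayes factor hypothesis tests for Pearson
    correlations and t-tests under informed (expert-elicited) and default
    prior distributions on the effect size.  Ships a registry of elicited
    beta and shifted-scaled t priors, histogram-method (roulette) prior
    fitting, exact reduced-likelihood and noncentral-t marginal
    likelihoods evaluated by adaptive quadrature on the log scale, a
    seeded Monte Carlo marginal-likelihood oracle, prior sensitivity
    analyses (direction agreement, evidence-category agreement, Bayes
    factor ratios), filtering and per-study sampling rules for
    meta-analytic study databases, and seeded synthetic database
    generators so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
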