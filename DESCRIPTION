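Package: ainlearn
Title: Active Information Measures of Learning and Knowledge Acquisition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies learning and knowledge acquisition of a rational
    agent with epistemic probability measures over a space of possible
    worlds (the parameters of a statistical model, one of which is true).
    Beliefs are Bayes posteriors constrained by a discernment partition;
    the active information statistic I+ = log P(A)/P0(A) compares the
    agent's belief in a proposition with a maximum-entropy ignorance
    baseline.  Provides static, sequential (strong/weak) and asymptotic
    verdict procedures distinguishing learning (true belief) from
    knowledge acquisition (justified true belief), hypothesis tests on I+
    with exact and Monte Carlo error rates, Bayesian posterior-odds
    equivalents, posterior-contraction diagnostics, and seeded worked
    experiments (coin tossing, student assessment, historical dating,
    weather forecasting, study replication, causal inference under
    unmeasured confounding).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
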