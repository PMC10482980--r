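Package: cpmpt
Title: Multinomial Cooperation-and-Punishment Model for Prisoner's
    Dilemma Games with Costly Punishment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits the multinomial processing tree (MPT) model that
    decomposes behavior in a one-shot Prisoner's Dilemma game with a
    costly punishment option into cooperation (C), moral punishment
    (P_moral), hypocritical punishment (P_hypocritical), antisocial
    punishment (P_antisocial), and an unspecific punishment bias (b).
    Provides multi-group maximum-likelihood estimation with cross-group
    equality constraints, likelihood-ratio G-squared goodness-of-fit and
    nested delta-G-squared hypothesis tests with Cohen's effect size w,
    expected-information standard errors, noncentral chi-square power
    analysis (achieved power, sensitivity, a-priori sample size), a
    trial-level game simulator with the payoff rules of the paradigm,
    a parameter-recovery harness, and an end-to-end analysis pipeline
    from trial-level CSV logs to a report of the full test battery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
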