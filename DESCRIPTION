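Package: bayesprevalence
Title: Bayesian Inference of Population Prevalence from Within-Participant Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the proportion of a population that would show an
    experimental effect (the population prevalence, or within-participant
    replication probability) from the number of participants individually
    significant at a controlled false-positive rate. Provides the
    truncated-beta posterior over prevalence with MAP estimates and highest
    posterior density intervals, exact binomial tests of the global and
    majority prevalence nulls, Monte-Carlo posteriors for prevalence
    differences between populations or between paired tests, a simulator of
    ERP-like multi-trial experiments for contrasting prevalence inference
    with population-mean inference, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
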