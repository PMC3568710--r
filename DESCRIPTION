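Package: valprob
Title: Statistical Validation of Significant Result Lists in High-Throughput
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies whether a manually confirmed random subsample of
    significant -omics results supports the false discovery rate (FDR)
    claimed by the original high-throughput analysis. Implements the
    Beta-Binomial conjugate posterior for the true false-discovery
    proportion, the resulting validation probability and equal-tailed
    credible intervals, bootstrap confidence intervals for the validation
    probability, minimum validation sample-size design, a deterministic
    cost and duration model for qPCR confirmation experiments (TaqMan and
    SYBrGreen chemistries), and a simulation engine for studying the
    operating characteristics of the validation probability under
    errorless, noisy, and misspecified validation scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
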