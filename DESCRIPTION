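Package: irgpair
Title: Immune-Related Gene-Pair Prognostic Signatures for Censored Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates prognostic risk signatures from within-sample
    orderings of immune-related gene pairs. Expression values are reduced to
    binary indicators (1 when the first gene of a pair is expressed strictly
    above the second in the same sample), which makes the features invariant to
    any per-sample monotone transformation and hence robust to cross-platform
    batch effects. The package provides the pair binarization and frequency
    filter, a univariate Cox screen, L1-penalized Cox signature fitting with
    cross-validated penalty selection, risk scoring and cutoff-based
    stratification, Kaplan-Meier / log-rank / Cox / time-dependent ROC
    evaluation, tumor mutation burden, association statistics for immune
    feature tables, a synthetic cohort generator for end-to-end testing, and a
    packaged 30-pair bladder-cancer signature.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
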