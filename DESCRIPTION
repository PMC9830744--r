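Package: survefs
Title: Ensemble Feature Selection for Right-Censored Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Homogeneous ensemble feature selection for survival analysis with
    censored outcomes. Base selectors (a univariate Cox concordance filter,
    penalised Cox regression, survival random forests) are applied to bootstrap
    resamples of the training data and the resulting rankings are combined with
    one of five aggregators: mean rank, mean weight, Robust Rank Aggregation,
    the Threshold Algorithm and MedRank. Selected-subset cut-offs include fixed
    fractions, the 75% quantile of importance scores, one-dimensional kernel
    density clustering, and random permutation probes. A repeated, stratified
    cross-validation harness scores each configuration by the concordance index
    of a ridge Cox model fitted on the selected features, together with the
    relative weighted consistency of the selected subsets, and a synthetic
    data generator with a planted set of prognostic features makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    ranger,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
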