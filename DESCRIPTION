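Package: mptdc
Title: Multinomial Processing Tree Models with Discrete and Continuous
    Variables for Recognition Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and fits multinomial processing tree models that jointly
    carry discrete and discretized continuous variables (MPT-DC) for
    old/new recognition memory: the two-high-threshold (2HT) and
    signal-detection (SDT) model families, each optionally extended with
    three-point confidence-rating bins and fast/slow response-time bins
    obtained by per-subject log-normal quantile discretization.  Provides
    maximum-likelihood estimation with Hessian-based standard errors,
    Pearson chi-squared and likelihood-ratio fit statistics, parametric
    bootstrap goodness-of-fit tests, AIC/AICc model comparison with
    selection crosstabs and phi effect sizes, and simulation tools for
    parameter- and model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
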