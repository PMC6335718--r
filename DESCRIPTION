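Package: kbdassoc
Title: Clinical Variable and Gene Expression Association Analysis for
    Kashin-Beck Disease Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Case-control association analysis linking clinical variables to
    gene expression in Kashin-Beck disease (KBD), an endemic osteoarthropathy.
    Implements a two-channel microarray differential-expression screen with an
    error-function (Erfc) p-value on standardized log ratios and a strict
    2-fold/0.5-fold call rule; clinical severity indexes (Manouvrier's skelic
    index, metacarpal length/breadth and length/height indexes); 2x2
    contingency analysis with uncorrected Pearson chi-square, exact
    hypergeometric (Fisher) p-values in one-sided and two two-sided variants,
    and Woolf logit confidence intervals for odds ratios; rank and parametric
    group comparisons; an in-package iteratively reweighted least squares
    logistic regression with Wald inference and separation diagnostics; and a
    synthetic cohort generator with an exact table-replay mode and a
    latent-severity model mode for parameter-recovery testing. A pipeline
    orchestrates screen, correlation, univariate and multivariable stages and
    verifies the built-in published contingency-table fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
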