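Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) toolkit for
    GWAS summary statistics: harmonization of exposure and outcome effect
    estimates to a common effect allele, instrument selection with strength
    and power gates, the five standard causal estimators (inverse-variance
    weighted, MR-Egger, weighted median, weighted mode, simple mode),
    MR-PRESSO pleiotropy residual-sum-and-outlier tests, Steiger
    directionality tests, multivariable MR, Benjamini-Hochberg false
    discovery rate control, inverse-variance meta-analysis across
    replication cohorts, a minimal LD-score regression, and hypergeometric
    metabolite pathway over-representation analysis. A synthetic
    summary-statistics generator with known ground truth makes every stage
    testable without consortium downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
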