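Package: orhomog
Title: Tests of Homogeneity of Odds Ratios in Multicenter Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tests of homogeneity of odds ratios across K independent 2x2
    contingency tables from multicenter clinical trials or meta-analyses:
    the Breslow-Day test, the DerSimonian-Laird Q statistic, and a
    likelihood-ratio test from a logistic-normal mixed model fitted by
    marginal maximum likelihood with Gauss-Hermite quadrature, using the
    50:50 chi-square mixture null appropriate for a variance component on
    the boundary. Includes a logistic-normal simulator for balanced and
    unbalanced multicenter designs and a Monte-Carlo engine for estimating
    empirical type I error and power of the three tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
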