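Package: weakivmr
Title: Many Weak Instruments Methods for Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Instrumental-variable estimation for Mendelian randomization
    studies that use many genetic variants, each only weakly associated with
    the exposure. Implements the GMM family of estimators (OLS, two-stage
    least squares, two-step GMM, LIML, and the continuously updating
    estimator), allele-score instruments, weak-instrument diagnostics
    (first-stage F, partial R-squared, concentration parameter, theoretical
    bias approximations for 2SLS and LIML), standard errors corrected for
    many weak instruments (Bekker for LIML, Newey-Windmeijer for CUE),
    specification tests (Sargan, Hansen J, Hausman), and a Monte Carlo
    engine for studying estimator bias and test size under a genotype-based
    data-generating process.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
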