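Package: lloqci
Title: Mean Estimation and Confidence Intervals for Data Below Limits of Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Maximum likelihood estimation of distribution means from samples
    left-censored by one or more lower limits of quantification (LLOQs), for
    normally, exponentially and Poisson distributed measurements. Implements
    the censored-sample likelihood, the half-LLOQ simple-imputation comparator,
    asymptotic parametric and bias-corrected accelerated (BCa) bootstrap
    confidence intervals for the mean, and a Monte Carlo engine evaluating
    coverage proportion, interval width, bias and root mean squared error of
    the interval estimators under configurable censoring designs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
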