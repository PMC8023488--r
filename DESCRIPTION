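Package: wtexpd
Title: The Weibull-Truncated Exponential Distribution for Lifetime Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Density, distribution, quantile, hazard, random generation,
    moments, entropy and order statistics for the Weibull-truncated
    exponential distribution (W-TEXPD), a left-truncated lifetime model
    with location tau, shape beta and an identifiable scale ratio
    lambda = alpha/theta. Maximum-likelihood fitting with analytic score,
    observed Fisher information and asymptotic (normal and log-normal)
    confidence bounds; baseline Weibull, Gamma, Exponential and truncated
    Exponential fits; model comparison by AIC/BIC and the
    Kolmogorov-Smirnov, Cramer-von Mises and Anderson-Darling statistics;
    a Monte-Carlo bias/MSE study of the estimators; five classical
    reliability and environmental datasets; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr
Config/testthat/edition: 3
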