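Package: attencor
Title: Bias and Correction of Pearson Correlation Under Measurement Error
Version: 0.1.0
Authors@R:
    person("attencor", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how measurement error corrupts the Pearson
    correlation coefficient and for correcting the induced bias. Implements
    additive, multiplicative, combined ("realistic") and generalized
    correlated error models for bivariate and multivariate normal signals:
    simulators with component-wise random-number streams, closed-form
    expected correlation and attenuation coefficients, classification of the
    bias regime (attenuation, inflation, sign flip) with the limiting
    surfaces separating the regimes, and disattenuation estimators that
    invert the bias formulas given known error-variance components. Also
    provides the simulation experiments commonly used to illustrate these
    effects: correlation-network inference on enzyme-kinetics profiles,
    technical-replicate averaging, Monte-Carlo envelopes of the expected
    correlation, and corrected-correlation recovery on synthetic
    metabolomics-like covariance structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
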