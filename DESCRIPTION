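Package: cpmult
Title: Conditional Predictive p-Values for Overdispersed Multinomial Count Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tests equality of two discrete populations when one arm delivers
    plain multinomial counts and the other is doubly overdispersed: a Poisson
    population bottleneck followed by Dirichlet-multinomial clonal growth, as
    arises in HPRT mutant T-cell receptor repertoire assays grown in mass
    culture. Implements the conditional predictive p-value (posterior
    predictive ordinate test conditioning on the mutant arm only), a
    Metropolis-Hastings block sampler for the latent bottleneck counts,
    population frequencies, and growth overdispersion, moment-matched
    Dirichlet approximation of the posterior, Monte Carlo Fisher and
    simulation-approximated likelihood-ratio baselines, chi-squared asymptotics
    for the centered multinomial log-mass, and an operating-characteristics
    simulation harness. Ships the six-patient J-region CDR3 count tables as a
    packaged fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
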