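Package: srctdesign
Title: Bayesian Design, Monitoring and Analysis of Small Randomized
    Comparative Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Conjugate beta-binomial inference and design tools for small
    randomized comparative trials (20-60 patients, 2-4 arms): posterior
    means, equal-tailed credible intervals, posterior distributions of the
    difference of two independent beta random variables with improvement
    probabilities Pr(theta_E > theta_S + delta | data), posterior-probability
    safety and futility stopping rules with their equivalent integer trigger
    boundaries, exact and simulated operating characteristics (early-stopping
    probabilities, sample-size distributions, enrichment and final arm
    selection), simulation-based decision-cutoff calibration, permuted-block
    and stratified randomization plans, and sample-size exploration tables.
    Includes a command-line interface and a seeded patient-level synthetic
    trial generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
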