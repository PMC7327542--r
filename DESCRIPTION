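Package: niadhere
Title: Non-Inferiority Trial Simulation and Analysis Under Non-Adherence
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-arm non-inferiority trials with binary outcomes
    under configurable non-adherence mechanisms (crossover to the opposite
    arm or switching to an inferior alternative treatment) and confounding
    of adherence and outcome. Provides intention-to-treat, per-protocol,
    inverse-probability-weighted, standardised and instrumental-variable
    (Wald) analyses with non-inferiority decision rules, Monte-Carlo
    operating characteristics with closed-form normal-approximation
    oracles, analytic and simulation-based power and sample-size
    calculation, and simulation of consecutive non-inferiority trials to
    quantify biocreep.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml, pracma
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
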