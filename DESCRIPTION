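Package: alkmeta
Title: Evidence Synthesis for ALK-Inhibitor Trials in ALK-Positive NSCLC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-treatment evidence synthesis of ALK-inhibitor
    trials in ALK-rearranged non-small cell lung cancer. Implements Bayesian
    random-effects network meta-analysis with a Metropolis-within-Gibbs
    sampler, league tables, rank probabilities and Brooks-Gelman-Rubin
    convergence diagnostics; classical fixed/random-effects pooling of odds
    ratios, hazard ratios, proportions and medians with a
    heterogeneity-driven model-selection rule; reconstruction of pseudo
    individual-patient data from digitized Kaplan-Meier curves with pooled
    survival curves and log-rank tests; and Egger/Begg publication-bias
    diagnostics. Includes seeded synthetic-data generators with known ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
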