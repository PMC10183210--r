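Package: orcaforage
Title: Individual Foraging Analysis from Killer Whale Bio-Logging Tags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for high-resolution bio-logging (DTAG-class)
    deployments on fish-eating killer whales. Detects dives from depth records,
    partitions them into descent, bottom, and ascent phases, computes the
    kinematic signatures of prey pursuit (normalized jerk peak, roll at jerk
    peak, circular variance in heading), classifies echolocation click trains
    by inter-click interval, calibrates acoustically-validated prey-capture
    filters at 100% sensitivity, dead-reckons GPS-corrected pseudotracks with
    bathymetry lookup, and summarizes per-deployment foraging metrics. Group
    comparisons use Poisson, negative-binomial (linear mean-variance), beta,
    and Gaussian mixed models with offsets, AIC-based random-structure
    selection, likelihood-ratio term deletion, and Tukey-style contrasts.
    Includes a synthetic deployment generator with ground-truth labels and a
    packaged deployment summary table for reproducible examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    glmmTMB,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
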