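Package: nichemax
Title: Maximum-Entropy Niche Modelling with Range-Transfer Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Presence-only species distribution modelling with a
    maximum-entropy (Gibbs) model fitted by L1-regularized convex
    optimization over a background sample. Derives the ten classical
    bioclimatic predictors from monthly climate grids, samples replicated
    pseudo-presence point sets from range masks, thresholds replicate
    suitability maps by minimum training presence (MTP) and maximum
    training sensitivity plus specificity (MTSS), evaluates transfer
    across time periods and regions (AUC, Cohen's kappa), and diagnoses
    non-analog climate via clamping and envelope novelty counts. Ships a
    synthetic-landscape generator with known ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    sp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
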