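Package: pshare
Title: Patient-Sharing Physician Networks and Attributed-Triad ERGMs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds undirected patient-sharing networks among office-based
    physicians from encounter-level claims data, splits ties into a
    physician-induced channel (referral-mediated) and a patient-induced
    channel (no referral documentation), and fits exponential random graph
    models whose statistics include role-attributed closed triads and open
    chains over the general-practitioner/specialist dichotomy, alternating
    k-stars and alternating two-paths, actor-covariate activity and
    (mis)match effects, and dyadic covariates such as pairwise travel
    times. Estimation is by maximum pseudo-likelihood and by Monte Carlo
    maximum likelihood with Robbins-Monro stochastic approximation,
    optionally conditioning on the observed number of ties via tie-swap
    sampling. Includes a synthetic claims generator with ground-truth
    metadata for validation, and simulation-based goodness-of-fit reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
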