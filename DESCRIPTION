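Package: campaignsim
Title: Agent-Based Planning of Preventive-Health Campaigns in Older Adults
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-layer network agent-based model for planning preventive
    campaigns (influenza vaccination, routine health screening) in older
    adults. Builds a synthetic matched survey population segmented by a
    latent class model of media and social profiles, embeds agents in an
    offline degree-targeted graph plus an online small-world graph, and
    simulates monthly awareness and adoption dynamics with media exposure,
    social spillover and threshold reinforcement. Fifteen prespecified
    channel-allocation, budget, personalization and loss-framing scenarios
    are compared by Monte Carlo replication against distributional-equity
    guardrails (minimum class adoption, 90-10 gap, relative disparity),
    with grid-search calibration to survey uptake targets, internal
    validation diagnostics (Brier score, calibration slope, decile
    reliability) and rank-stability sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    igraph,
    optparse
Config/testthat/edition: 3
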