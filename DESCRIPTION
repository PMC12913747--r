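Package: sinucost
Title: Long-Term Cost-Utility Modelling of Endoscopic Sinus Surgery for
    Chronic Rhinosinusitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-utility modelling for chronic
    rhinosinusitis (CRS): a perioperative decision tree for endoscopic
    sinus surgery (ESS) feeding a ten-state, utility-binned Markov cohort
    model evaluated over a multi-decade horizon. Provides EQ-5D scoring
    and utility binning, estimation of entrance distributions and
    transition matrices from longitudinal utility panels, deterministic
    cohort evaluation and seeded individual-level microsimulation,
    incremental cost-effectiveness ratios (ICERs) with dominance
    classification, one-way and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves and ICER-plane quadrant
    summaries, and a synthetic-cohort generator so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
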