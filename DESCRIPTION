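Package: mtshazard
Title: Chemical Health-Hazard Ranking and Scoring with the Mahalanobis-Taguchi System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks chemicals by health hazard from Globally Harmonized System
    (GHS) classification tables using the Mahalanobis-Taguchi System (MTS).
    Quantifies ordered GHS hazard categories into numeric scores, constructs a
    low-hazard reference ("unit") space, scores every chemical by its scaled
    Mahalanobis distance from the reference centre, partitions scores into
    hazard grades by four class-interval methods (equal interval, quantile,
    Fisher-Jenks natural breaks, geometric interval), and evaluates agreement
    with external chemical ranking and scoring methods via Pearson correlation
    and weighted Cohen's kappa, and validity against regulatory chemical lists.
    Includes a latent-Gaussian synthetic generator of GHS tables with
    controllable inter-endpoint correlation for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
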