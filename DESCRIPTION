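Package: rmcnemar
Title: Robust McNemar Tests for One-to-One Matched Observational Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Matching-algorithm-independent causal inference testing for
    one-to-one matched observational studies with binary outcomes. Builds
    exact-match partitions from coarsened covariates, computes closed-form
    extrema of the continuity-corrected McNemar statistic over all admissible
    pair assignments, identifies the robustness condition at which the extrema
    coincide, and profiles the uncertainty of the test over the number of
    matched discordant pairs. Includes a brute-force assignment enumerator as
    ground truth for small instances and seeded synthetic-data generators with
    planted partition structure and discordant capacities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
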