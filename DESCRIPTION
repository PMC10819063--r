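Package: pyrisk
Title: Retrospective Pyrethroid Risk Assessment from Food Monitoring and
    Human Biomonitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tiered retrospective risk assessment of pyrethroid insecticides.
    Predicts urinary metabolite concentrations from dietary exposure expressed
    as percentages of the acceptable daily intake (forward dosimetry),
    allocates shared urinary metabolites (DCCA, CFMP, 3-PBA) to the individual
    parent pyrethroids via food-monitoring-based contribution percentages,
    derives human biomonitoring guidance values and hazard quotients for
    individual, cumulative and combined exposure, and refines the assessment
    probabilistically by fitting distributions to reported percentiles and
    propagating them through a seeded Monte Carlo simulation. Includes a
    synthetic-data generator emulating diet-level dietary risk tables with
    limit-of-quantification censoring bounds and aggregated urinary percentile
    tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
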