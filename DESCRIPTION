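Package: ctdnadyn
Title: Tumor-Informed ctDNA Treatment-Response Monitoring from Droplet Digital PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies mutant circulating tumor DNA (ctDNA) from droplet
    digital PCR (ddPCR) droplet counts via Poisson correction, calls sample
    positivity, classifies two-timepoint ctDNA dynamics with a
    technical-variance-derived 30 percent change rule, and relates the
    resulting dynamics groups (alone and crossed with PD-L1 tumor proportion
    score) to progression-free survival, overall survival and durable
    clinical benefit using Kaplan-Meier, log-rank and Cox analyses.
    Includes cross-platform concordance statistics (Pearson r-squared,
    Cohen's kappa), evaluation of candidate follow-up timepoints from
    longitudinal series, and a synthetic-data generator that emulates the
    droplet-level and cohort-level statistical structure the analysis
    assumes, so every stage is testable without patient data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
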