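Package: curescan
Title: Genome-Wide Survival Association with a Mixture Cure Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Adaptive genome-wide association analysis for time-to-event
    outcomes in cohorts that contain long-term event-free survivors. For
    each SNP and genetic model, Kaplan-Meier long-term survival estimates
    of the genotype categories decide whether a semiparametric mixture
    cure model, a Cox proportional hazards model, or the log-rank test is
    fitted. Includes genotype quality control (Hardy-Weinberg exact test,
    missingness, minor allele frequency), genetic-model encoding with
    nested likelihood-ratio validity tests, covariate screening with
    backward selection, and a seeded synthetic cohort generator with
    cure-mixture outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils
Suggests:
    broom,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
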