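Package: crcscreen
Title: Markov Cohort Cost-Effectiveness Model for Colorectal Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic annual-cycle Markov cohort model comparing
    population-based colorectal cancer screening strategies -- yearly fecal
    immunochemical testing (FIT), yearly screening with the M3CRC fecal
    bacterial biomarker panel, and ten-yearly colonoscopy -- against no
    screening in a closed cohort followed from age 50 to 75. The package
    bundles the published base-case parameters (test operating
    characteristics, compliance, colonoscopy complication rates, stage
    distribution and stage-specific mortality, unit costs, age-specific
    incidence), generates a parametric all-cause-mortality life table,
    accumulates discounted costs and life-years, and reports comparative
    cost-effectiveness measures: cases prevented, life-years saved, cost per
    life-year saved, and pairwise incremental cost-effectiveness ratios with
    dominance handling. One-way and two-way deterministic sensitivity sweeps
    and threshold detection are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
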