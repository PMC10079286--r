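Package: screendisrupt
Title: Microsimulation of Disruptions to Population Cancer Screening Programmes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A microsimulation framework for evaluating the impact of
    service disruptions on organised breast, bowel (colorectal), and
    cervical cancer screening programmes. Generates synthetic screening
    cohorts, simulates simplified calibrated natural histories as
    continuous-time multistate processes, encodes programme screening
    logic (biennial mammography, biennial iFOBT with colonoscopy
    follow-up and surveillance, five-yearly primary HPV screening with
    colposcopy referral), applies disruption scenarios with
    capacity-constrained recovery and appointment prioritisation, and
    reports screens missed, cancer diagnoses, interval-cancer rates,
    programme sensitivity, stage shift, and downstream diagnostic
    service demand against a seed-paired status quo counterfactual.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
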