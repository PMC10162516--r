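Package: insuvent
Title: Closed-Loop Ventilation Control for Automated Insufflation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An in-silico testbed for studying the interaction between
    abdominal CO2 insufflation and mechanical ventilation. Provides a
    lumped-parameter virtual subject (CO2 and O2 kinetics plus respiratory
    mechanics under pneumoperitoneum), an incremental closed-loop controller
    that titrates respiratory rate toward an end-tidal CO2 target and
    inspired oxygen toward SpO2/oxygen-reserve-index bands, an automated
    experiment-protocol engine running intra-abdominal pressure staircases
    with breath holds, time-synchronized CSV run logs with controller
    replay, and post-run settling and pressure-interaction reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
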