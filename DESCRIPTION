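Package: adlminer
Title: Ambient-Sensor Detection of Activities of Daily Living by Association Rule Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts in-home ambient IoT sensor event streams (contact,
    motion, smart-plug and multi-channel environmental sensors) into
    order-independent sliding-window transactions, mines per-activity
    association rules with the apriori algorithm from sparse
    interview-style annotations, pools rules across participants, and
    applies them to detect four activities of daily living
    (eating/drinking, dressing, bathing, leaving the house) for
    participants who contributed no training data. Includes a synthetic
    cohort simulator with configurable routines, sensor signatures,
    background noise, door callers and a bathroom humidity model;
    reporting utilities for raw, day-normalised and proportional activity
    counts, a core-sensor ranking, and leave-one-participant-out
    evaluation; ggplot2 visualisations; and a command-line pipeline.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
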