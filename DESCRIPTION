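Package: driftwatch
Type: Package
Title: Multi-Agent Concept Drift Detection for Streaming Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Streaming concept-drift detection for multi-channel physiological
    sensor data such as electromyography (EMG). Implements an adaptive-windowing
    (ADWIN) change detector whose confidence parameter is regulated online from
    the observed drift rate, a Monitor-Analyse-Plan-Execute over shared
    Knowledge (MAPE-K) agent runtime with an append-only prediction store, a
    voting planner that suppresses single-channel false positives, and a
    reproducible synthetic EMG stream generator so the whole system can be
    exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
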