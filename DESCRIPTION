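Package: osmopulse
Title: Eulerian Division and Death Rate Estimation for Yeast Under
    Periodic Dual Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantification pipeline for time-lapse microfluidics
    experiments in which budding yeast is exposed to periodic dual
    fluctuations of hyperosmotic stress (sorbitol) and glucose
    availability.  Implements an Eulerian window-based estimator of
    per-capita division and death rates from tracked-nuclei tables,
    sliding-window instantaneous rates and phase-folded per-period
    profiles, reporter-fluorescence quantification (fold change,
    nuclear enrichment, fluorescein relative fluorescence), the
    periodic in-phase and alternating stress schedules, and an
    agent-based synthetic-data generator with ground truth for
    parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
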