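Package: llpsie
Title: Extraction and Evaluation of Liquid-Liquid Phase Separation
    Experiment Records from the Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mining liquid-liquid phase separation (LLPS)
    experiment records from the biomedical literature with multimodal
    large language models, and for scoring the extractions against
    curated ground truth. Provides tabular record types for the six
    commonly reported experimental conditions (protein name, protein
    concentration, RNA concentration, pH, temperature, phase status),
    rule-based unit normalization, composable prompt templates, a
    pluggable extraction pipeline with deterministic mock backends, an
    evaluator that matches extracted to label records by minimum-cost
    assignment over per-field normalized distances and reports per-field
    precision/recall/F1, and a synthetic scenario generator with
    by-construction expected tallies for offline benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
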