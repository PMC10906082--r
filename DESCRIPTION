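Package: seqcea
Title: Cost-Effectiveness of Treatment Sequencing with Semi-Markov Cohort Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for treatment-sequencing cost-effectiveness analysis in
    oncology: reconstruction of pseudo individual-patient data from digitized
    Kaplan-Meier curves with numbers at risk, maximum-likelihood fitting and
    information-criterion selection of parametric survival models, a
    semi-Markov cohort engine with tunnel states, time-dependent transition
    probabilities and age-matched background mortality, discounted cost and
    QALY accumulation, incremental cost-effectiveness ratios and dominance,
    one-way deterministic sensitivity analysis, and probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves. Includes a
    synthetic-data generator that emulates digitized trial survival curves,
    a life table and a fully specified two-strategy model configuration for
    first-line versus second-line sequencing of ALK inhibitors in
    ALK-positive non-small cell lung cancer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    flexsurv,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
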