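Package: evocea
Title: Cost-Effectiveness of Evolocumab Added to High-Intensity Statin
    Therapy in Secondary Cardiovascular Prevention
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness model comparing
    high-intensity atorvastatin monotherapy against atorvastatin plus the
    PCSK9 inhibitor evolocumab for secondary prevention of major adverse
    cardiovascular events, from the perspective of the Brazilian public
    health system (SUS). Provides a seeded synthetic-cohort generator
    matched to published sample marginals, translation of LDL cholesterol
    lowering into 10-year composite-event risk, human-capital costing of
    premature cardiovascular death, a discrete-time Markov cohort engine
    with discounting, incremental cost-effectiveness ratios, one-way
    deterministic sensitivity analysis, Monte Carlo probabilistic
    sensitivity analysis, and cost-effectiveness acceptability curves.
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
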