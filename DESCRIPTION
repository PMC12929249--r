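Package: phenolca
Title: EHR-Based Clinical Phenotyping of People with HIV via Latent Class Analysis
Version: 0.1.0
Authors@R:
    person("Maintainer", "Phenolca", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for identifying clinical phenotypes of
    people with HIV from electronic health record style data. Provides a
    synthetic cohort generator with known latent-class structure, rule-based
    extraction of clinical-note topics with windowed negation, visit-level
    categorical feature construction (age bins, diagnosis, social history,
    laboratory and retention-history indicators), care-retention and viral-load
    outcome labelling, a from-scratch EM estimator for latent class models of
    categorical indicators with AIC/BIC/SABIC/CAIC model selection, and
    per-class outcome comparison via contingency odds ratios, chi-squared and
    Kruskal-Wallis tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
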