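Package: aromarank
Title: Aroma-Active Compound Prioritization from Volatile Profiles and
    Sensory Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pipeline for sensory-driven prioritization of volatile
    organic compounds in fruit cultivars. Computes Relative Odor
    Activity Values (ROAV) from GC-MS relative-abundance tables and
    odor-threshold records (air-threshold priority with water
    fallback, arithmetic-mean resolution of multiple sources),
    classifies key and modifier odorants, quantifies shared and
    cultivar-specific compound sets and chemical-class composition,
    aggregates quantitative descriptive sensory panels with one-way
    ANOVA and compact-letter-display post hoc grouping, and performs
    joint sensory-chemical principal component analysis with
    loading-vector co-localization (angle and correlation criteria).
    Includes a seeded synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
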