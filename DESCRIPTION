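Package: uvbclines
Title: Geographic Clines in Allele Frequency Across UVB Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how allele frequencies of candidate variants
    differ between continental ancestry groups and along gradients of surface
    ultraviolet-B (UVB) irradiance. Provides fixation-index (FST) based variant
    selection, ancestry-group validation with skin-pigmentation markers,
    aggregation of gridded daily 305 nm irradiance to mean annual UVB per
    cohort location, cohort-size-weighted one-way ANOVA with Tukey-Kramer post
    hoc comparisons and compact letter displays, distribution-pattern and
    UVB-cline classification, and a Balding-Nichols synthetic-data generator
    for end-to-end testing of the pipeline.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
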