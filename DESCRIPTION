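Package: stacksdm
Title: Stacked Species Distribution Models for Climate-Driven Richness Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for stacked species distribution modelling of
    rare and endangered plants under climate-change scenarios. Fits per-species
    Random-Forest suitability models with matched pseudo-absences and repeated
    stratified cross-validation, selects species-specific thresholds by
    maximising the True Skill Statistic, quantifies climatic drivers with
    permutation importance (normalised scores, ranks, and top-three pattern
    typing), and stacks binarised range maps into grid- and zone-level species
    richness surfaces for a baseline and future warming scenarios. Ships a
    virtual-species generator (spatially structured bioclim-style climate
    grids, species with known niche responses, zone partitions) so every stage
    of the workflow is testable end to end without external data.
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
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
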