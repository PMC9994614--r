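Package: overyield
Title: Biodiversity Effect Partitioning and Trait Decomposition for
    Designed Grassland Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for designed biodiversity-ecosystem function
    experiments. Implements additive partitioning of overyielding into net,
    complementarity and selection effects from species-level biomass and
    monoculture references; community-weighted mean (CWM) trait construction
    with decomposition into composition/abundance and intraspecific
    adjustment components; sequential (Type-I) variance attribution of
    richness effects across the decomposed components; a two-order
    mixed-model comparison procedure separating species-richness from
    species-identity effects, including a neutralization classification; and
    a synthetic data generator that emulates a blocked dominance-experiment
    design with known ground-truth effect sizes for calibration and recovery
    testing.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
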