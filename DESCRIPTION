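Package: dielflux
Title: Transient Diel Metabolic Modeling from Time-Series Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building transient, diurnally resolved constraint-based
    metabolic models of photosynthetic microbes. Discrete diel transcriptome
    time series are fitted to a panel of parametric expression curves selected
    by small-sample-corrected AIC and combined into Akaike-weighted ensembles
    that can be queried at arbitrary times of day. The continuous curves drive
    time-varying reaction bounds through gene-protein-reaction Boolean logic
    (min for enzyme complexes, sum for isozymes), the biomass objective is
    decoupled into ten independently producible component pools tracked by
    proportional-integral controllers against diel composition setpoints, and
    day/night growth is simulated by iterated linear programming with starch
    storage and night-time catabolism. Includes expression-profile similarity
    scoring and Ward clustering, genome-wide single-knockout phenotype scans,
    and a compact synthetic photoautotroph model for testing, with readers for
    COBRA-JSON and SBML models.
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
    minpack.lm,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
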