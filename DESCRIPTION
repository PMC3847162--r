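Package: growthdyn
Title: Growth-Rate Phenotype Dynamics in Clonal Microbial Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and measurement of heritable growth-rate phenotypes in
    clonal microbial populations. Provides a lineage-selection Monte Carlo
    simulator (stable inheritance null model, with an optional metastable
    phenotype-switching mode) together with its closed-form Gaussian oracle; a
    microcolony time-lapse pipeline that segments frames, tracks colonies by
    centroid correlation, fits exponential area curves gated on goodness of
    fit, and summarizes growth-rate distributions with bootstrap errors;
    distribution standardization and scaling-collapse analysis with a
    variance-versus-mean quadratic law; plating-assay fraction-adapted
    statistics; and seeded synthetic-data generators for every input the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
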