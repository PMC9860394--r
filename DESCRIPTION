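Package: ptmquant
Title: Protein-Adjusted Differential Abundance of Posttranslational Modifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical relative quantification of posttranslational
    modification (PTM) sites from bottom-up mass-spectrometry proteomics.
    Feature-level intensities from enriched and global profiling runs are
    summarized per site and per protein (Tukey median polish or log-sum),
    modeled per target with linear or linear mixed-effects models, and PTM
    fold changes are adjusted for confounding changes in unmodified protein
    abundance, with standard errors combined across the two model fits and
    degrees of freedom from the Satterthwaite approximation. Includes
    ratio-based and moderated-variance baseline methods, ground-truth
    simulation and benchmarking utilities, and sample-size/power
    calculations for future PTM experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
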