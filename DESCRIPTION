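Package: stratamask
Title: Stratified Gene-Environment Association Simulation and Peptide
    Homology Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates cohorts under explicit gene-by-environment-by-cause
    penetrance models (the "fox and rabbits" parable of effect masking),
    analyses them with stratified and pooled 2x2 association statistics
    (odds ratios with zero-cell policies, Fisher/chi-square tests,
    Mantel-Haenszel pooling with Robins-Breslow-Greenland variance, Woolf
    heterogeneity, Benjamini-Hochberg adjustment), and quantifies how
    pooling can mask genuine stratum-specific genetic effects. A companion
    module scans a query peptide against protein sets for identical or
    physicochemically similar residue runs and calls antigenic segments
    from per-residue propensity scores with sliding-window smoothing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
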