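Package: omgsim
Title: Mock Multiomics Generation and Simulated Design-Build-Test-Learn Loops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the full Design-Build-Test-Learn cycle of metabolic
    engineering on stoichiometric models. Provides flux balance analysis with a
    deterministic least-norm tie-break, minimization of metabolic adjustment
    (MOMA) for engineered strains, dynamic batch-culture simulation with
    substrate depletion, generation of synthetic proteomics, transcriptomics
    and metabolomics tables from flux time series, categorical strain-design
    sampling by Latin hypercube, a probabilistic bootstrap-ensemble surrogate
    that recommends improved designs, and reading/writing of the five-column
    generic measurement interchange format used by the Experiment Data Depot.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rpart,
    quadprog,
    lhs,
    jsonlite,
    xml2,
    withr,
    tibble,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nloptr,
    optparse
Config/testthat/edition: 3
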