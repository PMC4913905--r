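Package: gsaccuracy
Title: Theoretical Accuracy of Genomic Selection and Its Computable Proxies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the accuracy of ridge-regression BLUP
    (RRBLUP/GBLUP) genomic prediction. Implements the exact theoretical
    accuracy of the RRBLUP predictor conditional on the training design, a
    QTL-free accuracy proxy built on the effective dimension of the ridge
    operator, and the classical proxies based on the effective number of
    independent chromosome segments (Me) and on the effective number of
    independent tests (Li & Ji). Includes a forward-in-time haploid
    random-mating simulator with Haldane recombination used to benchmark
    the proxies against empirical prediction accuracy, plus an experiment
    runner that reproduces the benchmark tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
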