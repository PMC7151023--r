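Package: asqpcr
Title: Mutant Allele Burden from Allele-Specific qPCR by the Comparative Cq Method
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the fraction of a somatic mutant allele (e.g. JAK2
    V617F) from paired allele-specific qPCR (AS-qPCR) quantification cycles
    using the comparative Cq (2^-ddCq) method, with or without an RNase P
    reference correction. Includes the assay-validation toolkit used in
    molecular diagnostics: standard-curve amplification efficiencies and
    slope-equality testing, probit-regression limit of detection, one-sample
    t-test limit of quantification, CLSI EP05-style precision variance
    components, Pearson/regression/Bland-Altman method comparison and 2x2
    qualitative agreement. A mechanistic simulator of AS-qPCR reaction pairs
    (binomial allele sampling, per-allele efficiencies, delayed wrong-allele
    crosstalk, Gaussian Cq noise, censoring at the total cycle count) makes
    every stage testable without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
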