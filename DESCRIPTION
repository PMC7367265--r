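Package: triadme
Title: Gene-Methylation and Parent-of-Origin-Methylation Interactions in
    Case-Parent Triads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Family-based tests for interaction between SNP relative risks
    and nearby DNA-methylation levels (GxMe), and between parent-of-origin
    effects and methylation (PoOxMe), from case-parent triads or
    parent-child dyads. Summarises CpG beta values over genomic regions
    (promoter, enhancer, gene body) near each SNP, stratifies samples into
    equally sized methylation strata, fits stratum-specific log-linear
    relative-risk models by maximum likelihood (conditional on parental
    mating type for complete triads, marginal with an EM algorithm for
    dyads), and tests for change of the log relative risk or log
    relative-risk ratio across strata with Wald and trend statistics.
    Includes control-triad diagnostics of the methylation-independence
    assumptions and a simulator of triad data with configurable
    methylation-genotype dependence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
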