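Package: enuscreen
Title: Simulation and Analysis of Three-Generation ENU Mutagenesis Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing chemical (ENU) mutagenesis
    screens in large animals. Provides a synthetic-data generator for
    mutagenized three-generation pedigrees (germline point mutations with a
    transition-biased spectrum, meiosis with recombination, reduced
    representation and SNP-array genotyping emulation), a Bayesian trio-based
    de novo mutation caller with genome-wide mutation-rate estimation,
    substitution-spectrum summaries, exact two-point parametric LOD linkage
    analysis on backcross pedigrees, a five-criteria causative-variant
    filtering cascade, and screen-design calculators (mutation-burden
    extrapolation, Mendelian segregation tests, recessive detection power,
    physiological reference ranges).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    withr,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
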